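# Structured-text persistence: models and reducers are stored as JSON with
# full double precision, a registry/content hash, and the configuration that
# produced them, so artifacts are reproducible and self-describing.

#' Hash an R object via its canonical JSON form
#'
#' @param x A list-like configuration object.
#' @return MD5 hex string.
#' @export
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Persist a fitted model bundle as structured text
#'
#' The bundle couples the PLS model with the reducer and token map that
#' produced its feature space, so prediction from raw epitope names is
#' self-contained.
#'
#' @param model A \code{pls_model}.
#' @param reducer A \code{reducer_model}.
#' @param token_map A \code{token_feature_map}.
#' @param path Output JSON path.
#' @param L_max Maximum peptide length of the encoding.
#' @param meta Optional named list of extra metadata (seeds, config hash).
#' @return The path, invisibly.
#' @export
save_model_bundle <- function(model, reducer, token_map, path, L_max = 10L,
                              meta = list()) {
  stopifnot(inherits(model, "pls_model"), inherits(reducer, "reducer_model"))
  payload <- list(
    format = "ncaabind_model",
    version = 1L,
    L_max = as.integer(L_max),
    d = reducer$d,
    meta = meta,
    pls = list(ncomp = model$ncomp, x_mean = model$x_mean,
               y_mean = model$y_mean, weights = model$weights,
               x_loadings = model$x_loadings, y_loadings = model$y_loadings,
               coefficients = model$coefficients),
    reducer = list(mean = reducer$mean, scale = reducer$scale,
                   loadings = reducer$loadings,
                   explained_variance_ratio = reducer$explained_variance_ratio,
                   d = reducer$d, descriptor_names = reducer$descriptor_names),
    token_map = list(tokens = rownames(token_map),
                     vectors = unclass(unname(token_map)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model bundle saved by [save_model_bundle()]
#'
#' @param path JSON path.
#' @return List with \code{model}, \code{reducer}, \code{token_map},
#'   \code{L_max}, \code{d}, \code{meta}.
#' @export
load_model_bundle <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ncaabind_model"))
    stop("not an ncaabind model file: ", path, call. = FALSE)
  model <- structure(list(ncomp = p$pls$ncomp,
                          x_mean = p$pls$x_mean, y_mean = p$pls$y_mean,
                          weights = as.matrix(p$pls$weights),
                          x_loadings = as.matrix(p$pls$x_loadings),
                          y_loadings = p$pls$y_loadings,
                          coefficients = p$pls$coefficients),
                     class = "pls_model")
  reducer <- structure(list(mean = p$reducer$mean, scale = p$reducer$scale,
                            loadings = as.matrix(p$reducer$loadings),
                            explained_variance_ratio = p$reducer$explained_variance_ratio,
                            d = p$reducer$d,
                            descriptor_names = p$reducer$descriptor_names),
                       class = "reducer_model")
  map <- as.matrix(p$token_map$vectors)
  rownames(map) <- p$token_map$tokens
  map <- structure(map, class = c("token_feature_map", "matrix", "array"))
  list(model = model, reducer = reducer, token_map = map,
       L_max = p$L_max, d = p$d, meta = p$meta)
}
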