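# Dimensionality reduction of the per-token descriptor space: z-score the
# descriptors (their magnitudes span orders of magnitude, from fragment
# counts to molecular weight), then PCA. The fit is over unique tokens, each
# counted once, matching the token -> feature-vector map the encoder builds.

#' Fit the descriptor-space PCA reducer
#'
#' Standardises each descriptor column (zero-variance columns get scale 1 so
#' they contribute nothing), then extracts the top \code{d} principal
#' components. Loading signs are fixed so each column's largest-magnitude
#' element is positive, making the fit reproducible across platforms.
#'
#' @param X Numeric matrix: one row per unique token, one column per
#'   descriptor.
#' @param d Number of components to keep (default 10).
#' @return A \code{reducer_model}: list with \code{mean}, \code{scale},
#'   \code{loadings} (p x d, orthonormal columns),
#'   \code{explained_variance_ratio} (length d, non-increasing), \code{d},
#'   and \code{descriptor_names}.
#' @export
fit_reducer <- function(X, d = 10L) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X) || any(!is.finite(X)))
    stop("descriptor matrix must be finite numeric", call. = FALSE)
  n <- nrow(X)
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1", call. = FALSE)
  if (n < d)
    stop(sprintf("only %d rows for d = %d components; use a smaller d", n, d),
         call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Z <- scale(X, center = mu, scale = sdv)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  if (ncol(pc$rotation) < d)
    stop(sprintf("matrix rank supports only %d components; use a smaller d",
                 ncol(pc$rotation)), call. = FALSE)
  total_var <- sum(pc$sdev^2)
  evr <- pc$sdev[seq_len(d)]^2 / total_var
  L <- pc$rotation[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(X), paste0("PC", seq_len(d)))
  structure(list(mean = mu, scale = sdv, loadings = L,
                 explained_variance_ratio = evr, d = d,
                 descriptor_names = colnames(X)),
            class = "reducer_model")
}

#' @export
print.reducer_model <- function(x, ...) {
  cat(sprintf("reducer_model: %d -> %d, %.2f%% variance covered\n",
              length(x$mean), x$d, 100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project descriptor rows through a fitted reducer
#'
#' @param reducer A \code{reducer_model}.
#' @param X Numeric matrix (or single row) in the descriptor space the
#'   reducer was fitted on.
#' @return Matrix of reduced coordinates, \code{nrow(X)} x \code{d}.
#' @export
reduce_descriptors <- function(reducer, X) {
  stopifnot(inherits(reducer, "reducer_model"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != length(reducer$mean))
    stop(sprintf("expected %d descriptor columns, got %d",
                 length(reducer$mean), ncol(X)), call. = FALSE)
  Z <- sweep(sweep(X, 2, reducer$mean, "-"), 2, reducer$scale, "/")
  out <- Z %*% reducer$loadings
  rownames(out) <- rownames(X)
  out
}

#' Build the token -> reduced-feature map
#'
#' Every registry token is mapped to its standardised, PCA-projected
#' \code{d}-vector; this map is the lookup table the peptide encoder uses.
#'
#' @param registry A \code{token_registry}.
#' @param reducer A \code{reducer_model} fitted on the same descriptor
#'   ordering.
#' @param tokens Tokens to map (default: all registry tokens).
#' @return A \code{token_feature_map}: numeric matrix with one named row per
#'   token and \code{d} columns.
#' @export
build_token_map <- function(registry, reducer, tokens = registry$token) {
  desc <- token_descriptor_matrix(registry, tokens)
  map <- reduce_descriptors(reducer, desc)
  structure(map, class = c("token_feature_map", class(map)))
}

#' Encode a tokenised peptide as a fixed-length feature vector
#'
#' Per-residue reduced vectors are concatenated N- to C-terminus and
#' right-padded with zeros to \code{L_max * d} entries, so a 9-mer at the
#' defaults yields 90 informative values followed by 10 appended zeros.
#'
#' @param tokens Character vector of residue tokens.
#' @param map A \code{token_feature_map}.
#' @param L_max Maximum peptide length the vector accommodates (default 10).
#' @return Numeric vector of length \code{L_max * ncol(map)} with attribute
#'   \code{n_residues}.
#' @export
encode_peptide <- function(tokens, map, L_max = 10L) {
  stopifnot(is.character(tokens), length(tokens) >= 1L)
  if (length(tokens) > L_max)
    stop(sprintf("peptide has %d residues but L_max is %d", length(tokens), L_max),
         call. = FALSE)
  unknown <- setdiff(tokens, rownames(map))
  if (length(unknown) > 0L)
    stop("token(s) not in feature map: ", paste(unknown, collapse = ", "),
         "; add them to the token registry", call. = FALSE)
  d <- ncol(map)
  v <- numeric(L_max * d)
  filled <- as.vector(t(map[tokens, , drop = FALSE]))
  v[seq_along(filled)] <- filled
  attr(v, "n_residues") <- length(tokens)
  v
}

#' Encode a filtered affinity dataset into the model feature matrix
#'
#' Parses and tokenises every record name, fits the descriptor reducer on
#' the unique tokens occurring in the dataset together with the registry's
#' canonical residues (each token counted once), builds the token map, and
#' assembles one fixed-length row per record.
#'
#' @param dataset An [affinity_dataset()].
#' @param registry A \code{token_registry} covering every token in the data.
#' @param d Reduced dimension per residue (default 10).
#' @param L_max Maximum peptide length (default 10).
#' @param reducer Optionally a pre-fitted \code{reducer_model} to reuse
#'   (e.g. at prediction time); when supplied, no refit happens.
#' @return List with \code{X} (n x \code{L_max * d} matrix), \code{y}
#'   (targets), \code{reducer}, \code{token_map}, and \code{peptides}
#'   (the parsed \code{modified_peptide} list).
#' @export
encode_dataset <- function(dataset, registry, d = 10L, L_max = 10L,
                           reducer = NULL) {
  stopifnot(inherits(dataset, "affinity_dataset"),
            inherits(registry, "token_registry"))
  n <- nrow(dataset$records)
  peptides <- vector("list", n)
  token_lists <- vector("list", n)
  for (i in seq_len(n)) {
    peptides[[i]] <- tryCatch(parse_epitope_name(dataset$records$name[i]),
                              error = function(e)
                                stop(sprintf("record %d ('%s'): %s", i,
                                             dataset$records$name[i],
                                             conditionMessage(e)), call. = FALSE))
    token_lists[[i]] <- tokenize(peptides[[i]])
  }
  canonical <- registry$token[!is_ncaa_token(registry$token)]
  fit_tokens <- union(sort(unique(unlist(token_lists))), canonical)
  fit_tokens <- fit_tokens[order(match(fit_tokens, registry$token))]
  unknown <- setdiff(fit_tokens, registry$token)
  if (length(unknown) > 0L) {
    culprit <- which(vapply(token_lists, function(t) any(t %in% unknown), logical(1)))[1]
    stop(sprintf("record %d ('%s') uses unregistered token(s): %s",
                 culprit, dataset$records$name[culprit],
                 paste(intersect(token_lists[[culprit]], unknown), collapse = ", ")),
         call. = FALSE)
  }
  desc <- token_descriptor_matrix(registry, fit_tokens)
  if (is.null(reducer)) reducer <- fit_reducer(desc, d = d)
  map <- structure(reduce_descriptors(reducer, desc),
                   class = c("token_feature_map", "matrix", "array"))
  X <- matrix(0, nrow = n, ncol = L_max * reducer$d)
  for (i in seq_len(n))
    X[i, ] <- encode_peptide(token_lists[[i]], map, L_max = L_max)
  colnames(X) <- sprintf("pos%02d_pc%02d",
                         rep(seq_len(L_max), each = reducer$d),
                         rep(seq_len(reducer$d), times = L_max))
  list(X = X, y = dataset$targets, reducer = reducer, token_map = map,
       peptides = peptides)
}
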