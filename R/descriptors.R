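# Descriptor backend: a pinned list of 208 two-dimensional physicochemical
# descriptors evaluated with RDKit through the bundled Python helper.
# Results are cached per SMILES for the lifetime of the R session, so the
# process-spawn cost is paid once per novel structure batch.

.ncaabind <- new.env(parent = emptyenv())

#' The pinned descriptor name list
#'
#' The packaged, fixed-order list of 208 two-dimensional physicochemical
#' descriptor names (molecular weight, partial-charge extrema, topological
#' indices, functional-group counts, ...). Pinning the list keeps the
#' feature count stable across descriptor-toolkit upgrades.
#'
#' @return Character vector of 208 names.
#' @export
descriptor_names <- function() {
  if (is.null(.ncaabind$descriptor_names)) {
    path <- system.file("extdata", "descriptor_names.txt", package = "ncaabind",
                        mustWork = TRUE)
    .ncaabind$descriptor_names <- readLines(path)
  }
  .ncaabind$descriptor_names
}

find_python <- function() {
  opt <- getOption("ncaabind.python", "")
  if (nzchar(opt)) return(opt)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no 'python' interpreter with RDKit found on PATH; ",
       "set options(ncaabind.python = ...)", call. = FALSE)
}

# one batch call to the helper; returns list(ok, n_heavy, values matrix)
run_descriptor_backend <- function(smiles) {
  script <- system.file("python", "descriptors.py", package = "ncaabind",
                        mustWork = TRUE)
  names_file <- system.file("extdata", "descriptor_names.txt",
                            package = "ncaabind", mustWork = TRUE)
  infile <- tempfile("smiles_", fileext = ".tsv")
  outfile <- tempfile("descr_", fileext = ".tsv")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste(seq_along(smiles), smiles, sep = "\t"), infile)
  status <- system2(find_python(),
                    c(shQuote(script), "--names", shQuote(names_file),
                      "--input", shQuote(infile), "--output", shQuote(outfile)),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(outfile))
    stop("descriptor backend failed (exit status ", status, ")", call. = FALSE)
  res <- utils::read.table(outfile, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("integer", "integer", "integer",
                                          rep("character", length(descriptor_names()))))
  vals <- as.matrix(res[, -(1:3), drop = FALSE])
  storage.mode(vals) <- "character"
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(NULL, colnames(vals))))
  list(ok = res$ok == 1L, n_heavy = res$n_heavy, values = num)
}

# cached parse/size status + raw descriptor rows, keyed by SMILES string
smiles_status <- function(smiles) {
  fetch_descriptor_rows(smiles)
  ok <- vapply(smiles, function(s) .ncaabind$cache[[s]]$ok, logical(1),
               USE.NAMES = FALSE)
  n_heavy <- vapply(smiles, function(s) .ncaabind$cache[[s]]$n_heavy, integer(1),
                    USE.NAMES = FALSE)
  list(ok = ok, n_heavy = n_heavy)
}

fetch_descriptor_rows <- function(smiles) {
  if (is.null(.ncaabind$cache)) .ncaabind$cache <- new.env(parent = emptyenv())
  novel <- unique(smiles[!vapply(smiles, function(s)
    !is.null(.ncaabind$cache[[s]]), logical(1), USE.NAMES = FALSE)])
  if (length(novel) > 0L) {
    res <- run_descriptor_backend(novel)
    for (i in seq_along(novel)) {
      .ncaabind$cache[[novel[i]]] <- list(ok = res$ok[i],
                                          n_heavy = res$n_heavy[i],
                                          values = res$values[i, ])
    }
  }
  invisible(NULL)
}

#' Compute the 208-descriptor vector for SMILES structures
#'
#' Evaluates the pinned descriptor list on each structure, in fixed order.
#' Non-finite descriptor values are imputed to 0 with a warning so the
#' downstream PCA always sees finite input.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Numeric matrix, one row per input structure, 208 named columns.
#'   Row names are the input SMILES.
#' @examples
#' \dontrun{
#' compute_descriptors("NCC(=O)O")[, "MolWt"]  # glycine, ~75.07
#' }
#' @export
compute_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L, !anyNA(smiles))
  fetch_descriptor_rows(smiles)
  bad <- smiles[!vapply(smiles, function(s) .ncaabind$cache[[s]]$ok, logical(1),
                        USE.NAMES = FALSE)]
  if (length(bad) > 0L)
    stop("cannot parse SMILES: ", paste(unique(bad), collapse = ", "), call. = FALSE)
  mat <- do.call(rbind, lapply(smiles, function(s) .ncaabind$cache[[s]]$values))
  rownames(mat) <- smiles
  nonfinite <- !is.finite(mat)
  if (any(nonfinite)) {
    warning(sprintf("%d non-finite descriptor value(s) imputed to 0", sum(nonfinite)),
            call. = FALSE)
    mat[nonfinite] <- 0
  }
  mat
}

#' Descriptor matrix for registry tokens
#'
#' @param registry A \code{token_registry}.
#' @param tokens Tokens to evaluate (default: all registry tokens).
#' @return Numeric matrix, rows named by token, 208 descriptor columns.
#' @export
token_descriptor_matrix <- function(registry, tokens = registry$token) {
  smiles <- registry_smiles(registry, tokens)
  mat <- compute_descriptors(unname(smiles))
  rownames(mat) <- tokens
  mat
}
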