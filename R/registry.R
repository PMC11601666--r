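#' The packaged default token registry
#'
#' Twenty canonical L-amino acids plus a curated starter set of
#' post-translationally modified / non-canonical residues (phospho-serine,
#' -threonine and -tyrosine, citrulline, hydroxyproline, methylated and
#' acylated lysines, nitro- and sulfotyrosine, and others), each as a free
#' amino acid SMILES with stereochemistry where known.
#'
#' @param validate Check every SMILES with the descriptor backend (parses,
#'   >= 4 heavy atoms). The packaged file is pre-validated, so this defaults
#'   to \code{FALSE}.
#' @return A \code{token_registry} data.frame with columns \code{token},
#'   \code{smiles}, \code{source}.
#' @export
default_registry <- function(validate = FALSE) {
  path <- system.file("extdata", "token_registry.tsv", package = "ncaabind",
                      mustWork = TRUE)
  reg <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  as_token_registry(reg, validate = validate)
}

as_token_registry <- function(df, validate = TRUE) {
  stopifnot(is.data.frame(df), all(c("token", "smiles") %in% names(df)))
  if (!"source" %in% names(df)) df$source <- NA_character_
  df <- df[, c("token", "smiles", "source")]
  bad <- !grepl("^[A-Z]$|^[A-Z]-[A-Z0-9]{2,6}$", df$token)
  if (any(bad))
    stop("registry tokens violating the token grammar: ",
         paste(df$token[bad], collapse = ", "), call. = FALSE)
  dup <- duplicated(df$token)
  if (any(dup))
    stop("duplicate registry tokens: ", paste(unique(df$token[dup]), collapse = ", "),
         call. = FALSE)
  if (validate) {
    chk <- smiles_status(df$smiles)
    if (any(!chk$ok))
      stop("registry SMILES failed to parse for token(s): ",
           paste(df$token[!chk$ok], collapse = ", "), call. = FALSE)
    small <- chk$ok & chk$n_heavy < 4L
    if (any(small))
      stop("registry SMILES with fewer than 4 heavy atoms for token(s): ",
           paste(df$token[small], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("token_registry", "data.frame"))
}

#' Load a token registry, merged over the packaged defaults
#'
#' The user file is tab-delimited with columns \code{token}, \code{smiles}
#' and optional \code{source}. Entries override the packaged defaults token
#' by token; the canonical 20 are therefore always present. An empty file
#' yields the packaged default registry.
#'
#' @param path Path to the user registry, or \code{NULL} for defaults only.
#' @param validate Validate user SMILES through the descriptor backend.
#' @return A \code{token_registry}.
#' @export
load_registry <- function(path = NULL, validate = TRUE) {
  base <- default_registry()
  if (is.null(path)) return(base)
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(base)
  user <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
  user <- as_token_registry(user, validate = validate)
  keep <- !(base$token %in% user$token)
  merged <- rbind(base[keep, , drop = FALSE], as.data.frame(user))
  merged <- merged[order(match(merged$token, c(base$token, user$token))), , drop = FALSE]
  as_token_registry(merged, validate = FALSE)
}

#' @export
print.token_registry <- function(x, ...) {
  cat(sprintf("token_registry: %d tokens (%d canonical, %d NCAA)\n",
              nrow(x), sum(!is_ncaa_token(x$token)), sum(is_ncaa_token(x$token))))
  invisible(x)
}

registry_smiles <- function(registry, tokens) {
  i <- match(tokens, registry$token)
  if (anyNA(i)) {
    missing <- unique(tokens[is.na(i)])
    stop("token(s) not in registry: ", paste(missing, collapse = ", "),
         "; extend the registry file with a SMILES for each", call. = FALSE)
  }
  stats::setNames(registry$smiles[i], tokens)
}
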