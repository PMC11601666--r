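#' Filter configuration for affinity exports
#'
#' Defaults reproduce the selection used throughout the package: the
#' HLA-A*02:01 allele, IC50 responses in nM, and at least one NCAA per
#' peptide. The long IEDB phrase
#' \code{"half maximal inhibitory concentration (IC50)"} and the short form
#' \code{"IC50"} are accepted as aliases for the response type.
#'
#' @param hla_allele HLA allele string to keep.
#' @param response_aliases Character vector of accepted "Response Measured"
#'   values (compared exactly after trimming).
#' @param require_ncaa Keep only peptides whose tokenisation contains at
#'   least one NCAA token.
#' @return A \code{filter_config} list.
#' @export
filter_config <- function(hla_allele = "HLA-A*02:01",
                          response_aliases = c("IC50",
                                               "half maximal inhibitory concentration (IC50)"),
                          require_ncaa = TRUE) {
  stopifnot(nzchar(hla_allele), length(response_aliases) >= 1L)
  structure(list(hla_allele = hla_allele,
                 response_aliases = response_aliases,
                 require_ncaa = isTRUE(require_ncaa)),
            class = "filter_config")
}

# canonical column names of the five columns of interest, with accepted aliases
EXPORT_COLUMNS <- list(
  name = c("Name", "Epitope - Name", "Description"),
  qualitative = c("Qualitative Measurement", "Qualitative Measure"),
  quantitative = c("Quantitative Measurement", "Quantitative measurement"),
  response_measured = c("Response Measured", "Assay - Response measured"),
  hla = c("HLA", "MHC Restriction", "Allele Name")
)

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("empty export file: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_comma <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_tab >= n_comma) "\t" else ","
}

#' Read an IEDB-style affinity export
#'
#' Locates the five columns of interest ("Name", "Qualitative Measurement",
#' "Quantitative Measurement", "Response Measured", "HLA") by header match,
#' ignores any extra columns, and turns empty cells into \code{NA}. The
#' delimiter (tab or comma) is sniffed from the header line unless given.
#' Censored quantitative values (\code{"<"}/\code{">"} prefixes) and
#' unparseable numeric cells are treated as absent with a warning.
#'
#' @param path Path to the delimited export.
#' @param delim \code{"\t"}, \code{","}, or \code{NULL} to sniff.
#' @return A data.frame of affinity records with columns \code{name},
#'   \code{qualitative}, \code{quantitative} (numeric, nM),
#'   \code{response_measured}, \code{hla}, and \code{epitope_iri} when the
#'   export carries one.
#' @export
read_export <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("export file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  raw <- utils::read.table(path, sep = delim, header = TRUE, quote = "\"",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = c("", "NA"))
  found <- names(raw)
  pick <- function(key) {
    hit <- intersect(EXPORT_COLUMNS[[key]], found)
    if (length(hit) == 0L)
      stop(sprintf("export is missing the '%s' column; headers found: %s",
                   EXPORT_COLUMNS[[key]][1], paste(found, collapse = ", ")),
           call. = FALSE)
    raw[[hit[1]]]
  }
  quant_raw <- pick("quantitative")
  quant <- rep(NA_real_, length(quant_raw))
  present <- !is.na(quant_raw)
  if (any(present)) {
    cleaned <- trimws(quant_raw[present])
    censored <- grepl("^[<>]", cleaned)
    if (any(censored))
      warning(sprintf("%d censored quantitative value(s) ('<'/'>') treated as absent",
                      sum(censored)), call. = FALSE)
    cleaned[censored] <- NA_character_
    cleaned <- gsub(",", "", cleaned, fixed = TRUE)  # "65,000" style separators
    parsed <- suppressWarnings(as.numeric(cleaned))
    bad <- !is.na(cleaned) & (is.na(parsed) | !is.finite(parsed) | parsed <= 0)
    if (any(bad))
      warning(sprintf("%d unparseable or non-positive quantitative value(s) treated as absent",
                      sum(bad)), call. = FALSE)
    parsed[bad] <- NA_real_
    quant[present] <- parsed
  }
  out <- data.frame(name = pick("name"),
                    qualitative = pick("qualitative"),
                    quantitative = quant,
                    response_measured = pick("response_measured"),
                    hla = pick("hla"),
                    stringsAsFactors = FALSE)
  if ("Epitope IRI" %in% found) out$epitope_iri <- raw[["Epitope IRI"]]
  attr(out, "delim") <- delim
  out
}

record_has_ncaa <- function(name) {
  tryCatch({
    pep <- suppressWarnings(parse_epitope_name(name))
    any(is_ncaa_token(tokenize(pep)))
  }, error = function(e) FALSE)
}

#' Apply the affinity filter cascade
#'
#' Keeps the records that (i) parse and contain at least one NCAA token,
#' (ii) carry a quantitative measurement, (iii) match the configured HLA
#' allele, and (iv) match the configured response type. Rules are applied in
#' that order; each rule's removal count (among rows surviving the previous
#' rules) is recorded in the attached \code{filter_report}, so kept + removed
#' always equals the input row count. Row order is preserved and the cascade
#' is idempotent.
#'
#' @param records Data.frame from [read_export()].
#' @param config A [filter_config()].
#' @return The surviving records, with attribute \code{filter_report}: a list
#'   with \code{n_input}, \code{removed} (named integer vector in rule
#'   order), and \code{n_kept}.
#' @export
apply_filters <- function(records, config = filter_config()) {
  stopifnot(is.data.frame(records), inherits(config, "filter_config"))
  keep <- rep(TRUE, nrow(records))
  removed <- c(ncaa = 0L, quantitative = 0L, hla = 0L, response = 0L)

  if (config$require_ncaa && nrow(records) > 0L) {
    ok <- vapply(records$name, record_has_ncaa, logical(1), USE.NAMES = FALSE)
    removed["ncaa"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  ok <- !is.na(records$quantitative) & is.finite(records$quantitative) &
    records$quantitative > 0
  removed["quantitative"] <- sum(keep & !ok)
  keep <- keep & ok

  ok <- !is.na(records$hla) & trimws(records$hla) == config$hla_allele
  removed["hla"] <- sum(keep & !ok)
  keep <- keep & ok

  ok <- !is.na(records$response_measured) &
    trimws(records$response_measured) %in% config$response_aliases
  removed["response"] <- sum(keep & !ok)
  keep <- keep & ok

  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- list(n_input = nrow(records),
                                     removed = removed,
                                     n_kept = nrow(out))
  out
}

#' Regression target: log10 of IC50 in nM
#'
#' Lower IC50 means tighter binding; the model works on the decadic log
#' scale, so 1 nM maps to 0 and 1000 nM to 3.
#'
#' @param ic50 Positive finite IC50 value(s) in nM.
#' @return \code{log10(ic50)}.
#' @export
to_target <- function(ic50) {
  if (!is.numeric(ic50) || any(is.na(ic50)) || any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("IC50 values must be positive and finite (nM)", call. = FALSE)
  log10(ic50)
}

#' Bundle filtered records with their regression targets
#'
#' @param records Filtered records (all with a quantitative value).
#' @return An \code{affinity_dataset}: list with \code{records} and the
#'   parallel numeric \code{targets} (log10 IC50 nM).
#' @export
affinity_dataset <- function(records) {
  stopifnot(is.data.frame(records))
  targets <- to_target(records$quantitative)
  structure(list(records = records, targets = targets), class = "affinity_dataset")
}

#' @export
print.affinity_dataset <- function(x, ...) {
  cat(sprintf("affinity_dataset: %d records, log10(IC50 nM) range [%.2f, %.2f]\n",
              nrow(x$records), min(x$targets), max(x$targets)))
  invisible(x)
}

#' Write records back out in the export dialect
#'
#' @param records Data.frame of affinity records (internal column names).
#' @param path Output path.
#' @param delim Field delimiter.
#' @export
write_export <- function(records, path, delim = "\t") {
  out <- data.frame(`Name` = records$name,
                    `Qualitative Measurement` = records$qualitative,
                    `Quantitative Measurement` = records$quantitative,
                    `Response Measured` = records$response_measured,
                    `HLA` = records$hla,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = delim, quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
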