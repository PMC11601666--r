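#' Parse an epitope name with modification annotations
#'
#' IEDB affinity exports label modified peptides as
#' \code{"SEQ + CODE(R#)"}: the text before \code{"+"} is the one-letter
#' base sequence, each \code{CODE} names a modification method and each
#' \code{R#} gives the one-letter residue and its 1-based position from the
#' N-terminus (so \code{"GILGFVFTL + OTH(L9)"} modifies the C-terminal
#' leucine of a 9-mer). Both the \code{"CODE1(R#), CODE2(R#)"} and the
#' \code{"CODE(R#, R#)"} multi-modification shapes are accepted and
#' normalised to one modification per position.
#'
#' @param name A single epitope name string.
#' @param min_length,max_length Accepted peptide length range. MHC-I ligands
#'   are 8--10 residues; the default upper bound allows 11 for robustness.
#' @return A \code{modified_peptide}: list with \code{base_sequence} (string)
#'   and \code{mods} (data.frame with columns \code{code}, \code{residue},
#'   \code{position}, ordered by position).
#' @examples
#' p <- parse_epitope_name("GILGFVFTL + OTH(L9)")
#' p$base_sequence
#' p$mods
#' tokenize(p)
#' @export
parse_epitope_name <- function(name, min_length = 8L, max_length = 11L) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(trimws(name)))
    stop("epitope name must be a single non-empty string", call. = FALSE)
  raw <- name
  text <- trimws(name)

  plus <- regexpr("+", text, fixed = TRUE)
  if (plus > 0L) {
    base <- trimws(substr(text, 1L, plus - 1L))
    annot <- trimws(substr(text, plus + 1L, nchar(text)))
  } else {
    base <- text
    annot <- ""
  }

  if (grepl("[a-z]", base)) {
    warning(sprintf("lowercase letters in sequence '%s' upcased", base), call. = FALSE)
    base <- toupper(base)
  }
  if (!grepl("^[A-Z]+$", base))
    stop(sprintf("malformed epitope name '%s': sequence part '%s' is not a run of one-letter codes",
                 raw, base), call. = FALSE)
  n <- nchar(base)
  if (n < min_length || n > max_length)
    stop(sprintf("peptide '%s' has length %d, outside the accepted %d-%d range",
                 base, n, min_length, max_length), call. = FALSE)
  letters_vec <- strsplit(base, "")[[1]]
  if (!all(letters_vec %in% AA_LETTERS))
    stop(sprintf("sequence '%s' contains non-canonical letters: %s", base,
                 paste(setdiff(letters_vec, AA_LETTERS), collapse = ", ")), call. = FALSE)

  mods <- data.frame(code = character(), residue = character(),
                     position = integer(), stringsAsFactors = FALSE)
  if (nzchar(annot)) {
    if (plus > 0L && !nzchar(base))
      stop(sprintf("malformed epitope name '%s': empty sequence before '+'", raw), call. = FALSE)
    # groups look like CODE( args ), separated by commas at top level
    group_re <- "^\\s*([A-Z0-9]{2,6})\\s*\\(([^()]*)\\)\\s*(,|$)"
    rest <- annot
    while (nzchar(rest)) {
      m <- regexec(group_re, rest)[[1]]
      if (m[1] == -1L)
        stop(sprintf("malformed modification annotation near '%s' in '%s'", rest, raw),
             call. = FALSE)
      lens <- attr(m, "match.length")
      code <- substr(rest, m[2], m[2] + lens[2] - 1L)
      args <- substr(rest, m[3], m[3] + lens[3] - 1L)
      for (item in strsplit(args, ",")[[1]]) {
        item <- gsub("\\s", "", item)
        if (!grepl("^[A-Za-z][0-9]+$", item))
          stop(sprintf("malformed residue-position item '%s' in '%s'", item, raw),
               call. = FALSE)
        residue <- toupper(substr(item, 1L, 1L))
        pos <- as.integer(substr(item, 2L, nchar(item)))
        if (pos < 1L || pos > n)
          stop(sprintf("modification position %d out of range for %d-mer '%s'", pos, n, base),
               call. = FALSE)
        if (letters_vec[pos] != residue)
          stop(sprintf("modification %s(%s%d) is inconsistent: residue at position %d of '%s' is %s",
                       code, residue, pos, pos, base, letters_vec[pos]), call. = FALSE)
        if (pos %in% mods$position)
          stop(sprintf("duplicate modification at position %d of '%s'", pos, raw), call. = FALSE)
        mods <- rbind(mods, data.frame(code = code, residue = residue, position = pos,
                                       stringsAsFactors = FALSE))
      }
      rest <- substr(rest, m[1] + lens[1], nchar(rest))
      rest <- sub("^\\s*", "", rest)
    }
  }
  mods <- mods[order(mods$position), , drop = FALSE]
  rownames(mods) <- NULL
  structure(list(base_sequence = base, mods = mods), class = "modified_peptide")
}

AA_LETTERS <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @export
print.modified_peptide <- function(x, ...) {
  cat(render_epitope_name(x), "\n")
  invisible(x)
}

#' Tokenize a modified peptide into per-residue tokens
#'
#' Unmodified positions yield their one-letter code; a position carrying a
#' modification yields \code{"<letter>-<CODE>"}. A token containing
#' \code{"-"} therefore denotes a non-canonical amino acid (NCAA).
#'
#' @param peptide A \code{modified_peptide} from [parse_epitope_name()].
#' @return Character vector of tokens, N- to C-terminus, one per residue.
#' @export
tokenize <- function(peptide) {
  stopifnot(inherits(peptide, "modified_peptide"))
  tokens <- strsplit(peptide$base_sequence, "")[[1]]
  if (nrow(peptide$mods) > 0L) {
    i <- peptide$mods$position
    tokens[i] <- paste0(tokens[i], "-", peptide$mods$code)
  }
  tokens
}

#' Render a modified peptide back to the export notation
#'
#' Produces the normalised \code{"SEQ + CODE(R#), CODE(R#)"} form (one group
#' per modified position, ordered N to C); re-parsing the result yields an
#' identical structure.
#'
#' @param peptide A \code{modified_peptide}.
#' @return A single string.
#' @export
render_epitope_name <- function(peptide) {
  stopifnot(inherits(peptide, "modified_peptide"))
  if (nrow(peptide$mods) == 0L) return(peptide$base_sequence)
  groups <- sprintf("%s(%s%d)", peptide$mods$code, peptide$mods$residue, peptide$mods$position)
  paste0(peptide$base_sequence, " + ", paste(groups, collapse = ", "))
}

#' Does a token name denote an NCAA?
#'
#' @param token Character vector of residue token names.
#' @return Logical vector, \code{TRUE} where the token carries a
#'   modification code.
#' @export
is_ncaa_token <- function(token) grepl("-", token, fixed = TRUE)

#' Read a plain-text peptide list
#'
#' One epitope name per line; blank lines and lines starting with
#' \code{"#"} are skipped.
#'
#' @param path File path.
#' @inheritParams parse_epitope_name
#' @return List of \code{modified_peptide} objects, named by the input line.
#' @export
read_peptide_list <- function(path, min_length = 8L, max_length = 11L) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- lapply(lines, parse_epitope_name, min_length = min_length, max_length = max_length)
  names(out) <- lines
  out
}
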