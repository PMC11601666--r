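# Synthetic IEDB-style exports from a known generative model, so the full
# filter -> encode -> regress pipeline is testable without any download.
# Records are 9/10-mer peptides carrying >= 1 NCAA, drawn as NCAA-substituted
# variants of a small set of parent scaffolds -- the structure a filtered
# single-allele affinity set actually has (a handful of parent epitopes, many
# modified analogues), which keeps the feature cloud low-dimensional the way
# real data is. Affinities follow a linear model in the assembled feature
# space with Gaussian noise on the log10(IC50 nM) scale, and distractor rows
# exercise each filter rule in isolation.

#' Specification of the synthetic affinity generator
#'
#' Defaults emulate the filtered study dataset: 166 records of 9- and
#' 10-mers (equal weight) drawn as NCAA-substituted variants of 5 parent
#' scaffolds, 28 NCAA tokens in play, mostly one modification per peptide,
#' log-affinities centred at 100 nM (log10 = 2) with signal standard
#' deviation 0.7 and noise chosen for a generative R-squared of 0.5, and 10
#' distractor rows per filter failure mode.
#'
#' Unless explicit \code{coefficients} are supplied, the generator draws
#' them in the span of the top \code{latent_rank} principal axes of the
#' realised feature matrix, so the response depends on exactly that many
#' informative latent directions; the signal is then standardised to
#' \code{signal_sd} around \code{center} and noise of standard deviation
#' \code{signal_sd * sqrt(1/target_r2 - 1)} is added. With explicit
#' \code{coefficients} (and \code{noise_sd}) the linear model is used raw.
#'
#' @param n_records Number of genuine (filter-surviving) records.
#' @param n_scaffolds Number of parent scaffold sequences the records are
#'   variants of (default 5).
#' @param length_weights Named numeric weights over peptide lengths
#'   \code{"9"} and \code{"10"} (drawn per scaffold).
#' @param n_ncaa_tokens Number of NCAA tokens sampled into the registry.
#' @param mods_per_peptide Named weights over modification counts
#'   \code{"1"} and \code{"2"}.
#' @param coefficients Optional explicit coefficient vector in the
#'   assembled feature space (length \code{L_max * d}).
#' @param noise_sd Noise standard deviation in log10 nM units; when
#'   \code{NULL} it is derived from \code{target_r2}.
#' @param target_r2 Generative R-squared used to set the noise level when
#'   \code{noise_sd} is \code{NULL} (default 0.5).
#' @param latent_rank Number of informative latent directions for drawn
#'   coefficients (default 3).
#' @param signal_sd Standard deviation of the noiseless signal (default
#'   0.7 log10 units).
#' @param center Mean log10(IC50 nM) of the noiseless signal (default 2,
#'   i.e. 100 nM).
#' @param distractors Named counts of corrupted rows per failure mode:
#'   \code{no_ncaa}, \code{missing_quantitative}, \code{wrong_hla},
#'   \code{wrong_response}.
#' @param d,L_max Encoder dimensions used by the reference encoding.
#' @param seed Integer seed driving every random draw.
#' @return A \code{generative_spec} list.
#' @export
generative_spec <- function(n_records = 166L,
                            n_scaffolds = 5L,
                            length_weights = c(`9` = 0.5, `10` = 0.5),
                            n_ncaa_tokens = 28L,
                            mods_per_peptide = c(`1` = 0.8, `2` = 0.2),
                            coefficients = NULL,
                            noise_sd = NULL,
                            target_r2 = 0.5,
                            latent_rank = 3L,
                            signal_sd = 0.7,
                            center = 2,
                            distractors = c(no_ncaa = 10L,
                                            missing_quantitative = 10L,
                                            wrong_hla = 10L,
                                            wrong_response = 10L),
                            d = 10L, L_max = 10L, seed = 0L) {
  stopifnot(n_records >= 10L, n_scaffolds >= 1L,
            is.null(noise_sd) || noise_sd >= 0,
            all(distractors >= 0L), signal_sd > 0,
            is.null(coefficients) || length(coefficients) == d * L_max,
            target_r2 > 0, target_r2 <= 1)
  nm <- c("no_ncaa", "missing_quantitative", "wrong_hla", "wrong_response")
  dist <- stats::setNames(rep(0L, 4L), nm)
  dist[names(distractors)] <- as.integer(distractors)
  structure(list(n_records = as.integer(n_records),
                 n_scaffolds = as.integer(n_scaffolds),
                 length_weights = length_weights,
                 n_ncaa_tokens = as.integer(n_ncaa_tokens),
                 mods_per_peptide = mods_per_peptide,
                 coefficients = coefficients, noise_sd = noise_sd,
                 target_r2 = target_r2, latent_rank = as.integer(latent_rank),
                 signal_sd = signal_sd, center = center,
                 distractors = dist, d = as.integer(d),
                 L_max = as.integer(L_max), seed = as.integer(seed)),
            class = "generative_spec")
}

#' Sample a token registry for simulation
#'
#' The canonical 20 plus \code{n_ncaa} NCAA entries sampled without
#' replacement from the packaged NCAA pool; deterministic given the seed.
#'
#' @param n_ncaa Number of NCAA tokens (0 to the pool size).
#' @param seed Integer seed.
#' @return A \code{token_registry} of \code{20 + n_ncaa} tokens.
#' @export
make_registry <- function(n_ncaa = 28L, seed = 0L) {
  full <- default_registry()
  canonical <- full[!is_ncaa_token(full$token), , drop = FALSE]
  pool <- full[is_ncaa_token(full$token), , drop = FALSE]
  n_ncaa <- as.integer(n_ncaa)
  if (n_ncaa < 0L || n_ncaa > nrow(pool))
    stop(sprintf("n_ncaa = %d outside the packaged pool size %d", n_ncaa, nrow(pool)),
         call. = FALSE)
  picked <- if (n_ncaa == 0L) pool[0, , drop = FALSE]
            else pool[sort(with_local_seed(seed, sample.int(nrow(pool), n_ncaa))), ,
                      drop = FALSE]
  as_token_registry(rbind(as.data.frame(canonical), as.data.frame(picked)),
                    validate = FALSE)
}

ncaa_parent_letter <- function(token) substr(token, 1L, 1L)

sample_peptides <- function(spec, registry) {
  ncaa_tokens <- registry$token[is_ncaa_token(registry$token)]
  if (length(ncaa_tokens) == 0L)
    stop("registry has no NCAA tokens to place", call. = FALSE)
  lens <- as.integer(names(spec$length_weights))
  scaffolds <- lapply(seq_len(spec$n_scaffolds), function(i) {
    len <- lens[sample.int(length(lens), 1L, prob = spec$length_weights)]
    sample(AA_LETTERS, len, replace = TRUE)
  })
  counts <- as.integer(names(spec$mods_per_peptide))
  peptides <- vector("list", spec$n_records)
  for (i in seq_len(spec$n_records)) {
    base <- scaffolds[[sample.int(spec$n_scaffolds, 1L)]]
    len <- length(base)
    n_mods <- counts[sample.int(length(counts), 1L, prob = spec$mods_per_peptide)]
    n_mods <- min(n_mods, length(ncaa_tokens), len)
    pos <- sort(sample.int(len, n_mods))
    toks <- sample(ncaa_tokens, n_mods)
    base[pos] <- ncaa_parent_letter(toks)  # make the annotation consistent
    mods <- data.frame(code = sub("^[A-Z]-", "", toks),
                       residue = ncaa_parent_letter(toks),
                       position = pos, stringsAsFactors = FALSE)
    peptides[[i]] <- structure(list(base_sequence = paste(base, collapse = ""),
                                    mods = mods), class = "modified_peptide")
  }
  peptides
}

#' Generate a synthetic IEDB-style export with known ground truth
#'
#' Samples peptides, encodes them with a reference reducer fitted on the
#' full registry, draws log10(IC50 nM) from the linear model described in
#' [generative_spec()], clamps IC50 to the 0.1--65,000 nM range, appends
#' the requested distractor rows (each corrupting exactly one filter field)
#' and shuffles deterministically.
#'
#' @param spec A [generative_spec()].
#' @param registry A \code{token_registry}; default samples one with
#'   [make_registry()] from the spec's seed.
#' @param path Optional output path; when given, the export is written as a
#'   tab-delimited file in the five-column schema.
#' @return List with \code{records} (data.frame in export schema, shuffled),
#'   \code{truth} (coefficients, intercept, noiseless targets, noise_sd,
#'   realized generative R-squared, indices of genuine rows after the
#'   shuffle), and \code{registry}.
#' @export
generate_affinity_data <- function(spec, registry = NULL, path = NULL) {
  stopifnot(inherits(spec, "generative_spec"))
  if (is.null(registry)) registry <- make_registry(spec$n_ncaa_tokens, spec$seed)

  state <- with_local_seed(spec$seed, {
    peptides <- sample_peptides(spec, registry)

    desc <- token_descriptor_matrix(registry)
    reducer <- fit_reducer(desc, d = spec$d)
    map <- structure(reduce_descriptors(reducer, desc),
                     class = c("token_feature_map", "matrix", "array"))
    X <- t(vapply(peptides,
                  function(p) encode_peptide(tokenize(p), map, L_max = spec$L_max),
                  numeric(spec$L_max * spec$d)))

    if (is.null(spec$coefficients)) {
      Xc <- scale(X, center = TRUE, scale = FALSE)
      V <- svd(Xc, nu = 0, nv = spec$latent_rank)$v
      beta_raw <- as.vector(V %*% stats::rnorm(spec$latent_rank))
      s_raw <- as.vector(X %*% beta_raw)
      sd_raw <- stats::sd(s_raw)
      beta <- spec$signal_sd * beta_raw / sd_raw
      noiseless <- spec$center + spec$signal_sd * (s_raw - mean(s_raw)) / sd_raw
      intercept <- spec$center - spec$signal_sd * mean(s_raw) / sd_raw
      sigma <- if (is.null(spec$noise_sd))
        spec$signal_sd * sqrt(1 / spec$target_r2 - 1) else spec$noise_sd
    } else {
      beta <- spec$coefficients
      noiseless <- as.vector(X %*% beta)
      intercept <- 0
      sigma <- if (!is.null(spec$noise_sd)) spec$noise_sd
               else if (spec$target_r2 == 1) 0
               else stats::sd(noiseless) * sqrt(1 / spec$target_r2 - 1)
    }
    y <- noiseless + stats::rnorm(spec$n_records, sd = sigma)
    ic50 <- pmin(pmax(10^y, 0.1), 65000)
    n_clamped <- sum(ic50 != 10^y)

    genuine <- data.frame(
      name = vapply(peptides, render_epitope_name, character(1)),
      qualitative = ifelse(ic50 < 500, "Positive", "Negative"),
      quantitative = ic50,
      response_measured = "half maximal inhibitory concentration (IC50)",
      hla = "HLA-A*02:01", stringsAsFactors = FALSE)

    rows <- list(genuine)
    dc <- spec$distractors
    if (dc["no_ncaa"] > 0L) {
      plain <- replicate(dc[["no_ncaa"]],
                         paste(sample(AA_LETTERS, 9L, replace = TRUE), collapse = ""))
      rows$no_ncaa <- data.frame(
        name = plain, qualitative = "Positive",
        quantitative = stats::runif(dc[["no_ncaa"]], 1, 1000),
        response_measured = "half maximal inhibitory concentration (IC50)",
        hla = "HLA-A*02:01", stringsAsFactors = FALSE)
    }
    corrupt_base <- function(n) genuine[sample.int(nrow(genuine), n, replace = TRUE), ,
                                        drop = FALSE]
    if (dc["missing_quantitative"] > 0L) {
      r <- corrupt_base(dc[["missing_quantitative"]])
      r$quantitative <- NA_real_
      rows$missing_quantitative <- r
    }
    if (dc["wrong_hla"] > 0L) {
      r <- corrupt_base(dc[["wrong_hla"]])
      r$hla <- "HLA-B*07:02"
      rows$wrong_hla <- r
    }
    if (dc["wrong_response"] > 0L) {
      r <- corrupt_base(dc[["wrong_response"]])
      r$response_measured <- "EC50"
      rows$wrong_response <- r
    }
    all_rows <- do.call(rbind, rows)
    rownames(all_rows) <- NULL
    genuine_flag <- rep(c(TRUE, FALSE), c(nrow(genuine), nrow(all_rows) - nrow(genuine)))
    ord <- sample.int(nrow(all_rows))
    list(records = all_rows[ord, , drop = FALSE],
         genuine_index = match(which(genuine_flag), ord),
         noiseless = noiseless, y = y, beta = beta, intercept = intercept,
         sigma = sigma, n_clamped = n_clamped)
  })

  records <- state$records
  rownames(records) <- NULL
  realized_r2 <- 1 - state$sigma^2 / stats::var(state$y)
  truth <- list(coefficients = state$beta, intercept = state$intercept,
                noiseless_targets = state$noiseless, noise_sd = state$sigma,
                generative_r2 = if (state$sigma == 0) 1 else realized_r2,
                n_clamped = state$n_clamped,
                # positions of genuine rows in the shuffled table, and the
                # original record id sitting at each of those positions
                genuine_rows = sort(state$genuine_index),
                genuine_ids = order(state$genuine_index))
  out <- list(records = records, truth = truth, registry = registry)
  if (!is.null(path)) {
    write_export(records, path, delim = "\t")
    out$path <- path
  }
  out
}
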