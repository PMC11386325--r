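# Runs of homozygosity: a two-state genotype-based HMM (autozygous vs
# Hardy-Weinberg), Viterbi decoding, segment calling, and F_ROH summaries.
#
# The HMM is deliberately simple and deterministic: two hidden states,
# genotype emissions (hom / het / missing), and distance-scaled transition
# probabilities so that sparse sites do not inflate switching costs. All
# arithmetic is in log space.

#' Parameters of the two-state ROH HMM
#'
#' @param p_het_in_roh emission probability of a heterozygous genotype
#'   inside an autozygous tract (residual error + mutation; default 0.005).
#' @param transition_per_bp per-bp probability of switching hidden state;
#'   the switch probability over a gap of g bp is `1 - (1 - t)^g`
#'   (default 5e-7).
#' @param p_het_hw het emission in the non-autozygous state when site
#'   frequencies are not used (default 0.35).
#' @param use_site_frequencies use per-site `2 p (1 - p)` as the
#'   non-autozygous het emission when allele frequencies are available
#'   (default `TRUE`).
#' @return list of class `roh_hmm_params`.
#' @export
roh_hmm_params <- function(p_het_in_roh = 0.005, transition_per_bp = 5e-7,
                           p_het_hw = 0.35, use_site_frequencies = TRUE) {
  stopifnot(p_het_in_roh > 0, p_het_in_roh < 1,
            transition_per_bp > 0, transition_per_bp < 1,
            p_het_hw > 0, p_het_hw < 1)
  structure(list(p_het_in_roh = p_het_in_roh,
                 transition_per_bp = transition_per_bp,
                 p_het_hw = p_het_hw,
                 use_site_frequencies = use_site_frequencies),
            class = "roh_hmm_params")
}

# log emission matrix, 2 x m, rows AZ / HW (internal)
.roh_log_emissions <- function(obs, params, het_freq = NULL) {
  m <- length(obs)
  p_hw <- if (params$use_site_frequencies && !is.null(het_freq)) {
    pmin(pmax(het_freq, 1e-4), 0.5)
  } else {
    rep(params$p_het_hw, m)
  }
  az <- ifelse(obs == "het", log(params$p_het_in_roh),
        ifelse(obs == "hom", log1p(-params$p_het_in_roh), 0))
  hw <- ifelse(obs == "het", log(p_hw),
        ifelse(obs == "hom", log1p(-p_hw), 0))
  rbind(AZ = az, HW = hw)
}

#' Viterbi decoding of autozygous state along one scaffold
#'
#' Finds the most probable hidden-state path over {AZ, HW} given per-site
#' genotype observations for one individual. Missing genotypes emit
#' probability 1 in both states (uninformative); transition probabilities
#' are scaled by the inter-site distance.
#'
#' @param obs character vector of per-site observations in
#'   `c("hom", "het", "missing")`.
#' @param positions strictly increasing 0-based site positions (bp).
#' @param params [roh_hmm_params()].
#' @param het_freq optional per-site expected het frequency `2 p (1 - p)`
#'   for the non-autozygous state.
#' @return character vector of states, `"AZ"` or `"HW"`, one per site.
#' @export
viterbi_roh <- function(obs, positions, params = roh_hmm_params(),
                        het_freq = NULL) {
  m <- length(obs)
  stopifnot(length(positions) == m,
            all(obs %in% c("hom", "het", "missing")))
  if (m < 2) return(rep("HW", m))
  if (any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  em <- .roh_log_emissions(obs, params, het_freq)
  g <- diff(positions)
  log_stay <- g * log1p(-params$transition_per_bp)
  log_switch <- log(-expm1(log_stay))
  delta <- matrix(-Inf, 2, m)
  psi <- matrix(1L, 2, m)
  delta[, 1] <- log(0.5) + em[, 1]
  for (t in 2:m) {
    for (j in 1:2) {
      cand <- delta[, t - 1] +
        ifelse(1:2 == j, log_stay[t - 1], log_switch[t - 1])
      psi[j, t] <- which.max(cand)
      delta[j, t] <- cand[psi[j, t]] + em[j, t]
    }
  }
  path <- integer(m)
  path[m] <- which.max(delta[, m])
  for (t in (m - 1):1) path[t] <- psi[path[t + 1], t + 1]
  c("AZ", "HW")[path]
}

#' Convert a state path to ROH segments
#'
#' Maximal runs of the AZ state become segments; a segment spans from the
#' first AZ site position to the last AZ site position + 1 (half-open).
#'
#' @param path state vector from [viterbi_roh()].
#' @param positions the matching site positions.
#' @param sample sample identifier recorded on each segment.
#' @param scaffold scaffold identifier.
#' @return data frame: `sample`, `scaffold`, `start`, `end`, `n_sites`.
#' @export
call_segments <- function(path, positions, sample = "sample",
                          scaffold = "scaffold") {
  stopifnot(length(path) == length(positions))
  empty <- data.frame(sample = character(), scaffold = character(),
                      start = numeric(), end = numeric(),
                      n_sites = integer(), stringsAsFactors = FALSE)
  if (!length(path)) return(empty)
  r <- rle(path == "AZ")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  az <- which(r$values)
  if (!length(az)) return(empty)
  data.frame(sample = sample, scaffold = scaffold,
             start = positions[starts[az]],
             end = positions[ends[az]] + 1,
             n_sites = r$lengths[az],
             stringsAsFactors = FALSE)
}

#' Fraction of the assessed genome in long ROH
#'
#' `F_ROH>L`: total length of segments at least `min_len` bp long, divided
#' by the assessed length. 100 kb captures cumulative inbreeding; 1 Mb
#' captures recent inbreeding.
#'
#' @param segments segment data frame from [call_segments()].
#' @param assessed_length denominator in bp (callable length by default
#'   in the pipeline).
#' @param min_len minimum segment length in bp (default 100 kb).
#' @return numeric fraction in \[0, 1\], `NA` when `assessed_length` is 0.
#' @examples
#' segs <- data.frame(start = c(0, 1e6), end = c(1.5e5, 3e6))
#' froh(segs, 1e7)        # 0.215
#' froh(segs, 1e7, 1e6)   # 0.2
#' @export
froh <- function(segments, assessed_length, min_len = 1e5) {
  if (is.na(assessed_length) || assessed_length <= 0) return(NA_real_)
  if (!nrow(segments)) return(0)
  len <- segments$end - segments$start
  sum(len[len >= min_len]) / assessed_length
}

#' Population mean ROH fractions
#'
#' @param summaries per-sample summary data frame with `f100kb`, `f1mb`
#'   columns (from [call_roh()]).
#' @return list with `f100kb` and `f1mb` arithmetic means across samples
#'   (`f1mb` is `NA` when undefined for all samples).
#' @export
population_froh <- function(summaries) {
  if (!nrow(summaries)) stop("no per-sample summaries")
  f1 <- summaries$f1mb
  list(f100kb = mean(summaries$f100kb),
       f1mb = if (all(is.na(f1))) NA_real_ else mean(f1, na.rm = TRUE))
}

#' Call ROH for every individual in a population
#'
#' Runs the Viterbi HMM per sample and scaffold, converts state paths to
#' segments, and summarizes `F_ROH>100kb` and `F_ROH>1Mb` per sample. Only
#' scaffolds at least `min_scaffold` bp long are assessed; `F_ROH>1Mb` is
#' undefined (`NA`) when no scaffold reaches 1 Mb, since such assemblies
#' cannot contain a 1 Mb segment.
#'
#' @param tab a [variant_table()].
#' @param index a [genome_index()].
#' @param params [roh_hmm_params()].
#' @param callable optional callable [interval_set()]; its width on the
#'   assessed scaffolds is the F_ROH denominator (scaffold span otherwise).
#' @param min_scaffold minimum scaffold length assessed (default 100 kb).
#' @return list with `segments` (all samples) and `summary` (one row per
#'   sample: `sample`, `assessed_length`, `f100kb`, `f1mb`).
#' @export
call_roh <- function(tab, index, params = roh_hmm_params(),
                     callable = NULL, min_scaffold = 1e5) {
  idx <- filter_scaffolds(index, min_scaffold)
  if (!nrow(idx)) stop("no scaffold passes the length filter")
  assessed <- if (is.null(callable)) sum(idx$length) else {
    full <- interval_set(idx$scaffold, rep(0, nrow(idx)), idx$length)
    interval_width(intersect_intervals(callable, full))
  }
  sc <- .site_counts(tab)
  p_hat <- ifelse(sc$n > 0, sc$x / sc$n, 0)
  het_freq_all <- 2 * p_hat * (1 - p_hat)
  seg_list <- list()
  for (smp in tab$samples) {
    g <- tab$geno[, smp]
    obs <- ifelse(is.na(g), "missing", ifelse(g == 1L, "het", "hom"))
    for (s in idx$scaffold) {
      i <- which(tab$sites$scaffold == s)
      if (!length(i)) next
      path <- viterbi_roh(obs[i], tab$sites$pos[i], params,
                          het_freq = het_freq_all[i])
      seg_list[[length(seg_list) + 1L]] <-
        call_segments(path, tab$sites$pos[i], sample = smp, scaffold = s)
    }
  }
  segments <- if (length(seg_list)) do.call(rbind, seg_list) else
    call_segments(character(), numeric())
  f1mb_defined <- any(idx$length >= 1e6)
  summary <- do.call(rbind, lapply(tab$samples, function(smp) {
    segs <- segments[segments$sample == smp, , drop = FALSE]
    data.frame(sample = smp, assessed_length = assessed,
               f100kb = froh(segs, assessed, 1e5),
               f1mb = if (f1mb_defined) froh(segs, assessed, 1e6)
                      else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(segments = segments, summary = summary)
}
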