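# Windowed diversity estimators: folded SFS, Watterson's theta, nucleotide
# diversity, Tajima's D, heterozygosity, and species-level summaries.
#
# Estimators operate on called genotypes. Chromosome count n = 2 x number of
# individuals (diploid autosomes). Per-site n varies with missingness: pi
# uses the per-site n, theta_W uses the modal n among retained sites so the
# S / a1(n) form stays exact; sites below the call-rate threshold are
# dropped.

#' Harmonic-number constants for Tajima's D
#'
#' The eight constants of the mutation-drift-equilibrium variance
#' normalization, derived from the number of sampled chromosomes `n`:
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i` in `1..n-1`, and the derived
#' `b1, b2, c1, c2, e1, e2`.
#'
#' @param n number of chromosomes (>= 2).
#' @return named list with elements `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

# per-site alternate-allele counts and called chromosome numbers (internal)
.site_counts <- function(tab) {
  called <- !is.na(tab$geno)
  data.frame(scaffold = tab$sites$scaffold, pos = tab$sites$pos,
             x = rowSums(tab$geno, na.rm = TRUE),
             n = 2L * rowSums(called),
             stringsAsFactors = FALSE)
}

#' Folded site frequency spectrum by direct counting
#'
#' Minor-allele counts per segregating site; monomorphic sites contribute
#' nothing. Sites with call rate below `min_call_rate` are excluded.
#'
#' @param tab a [variant_table()].
#' @param region optional [interval_set()] restricting the sites.
#' @param min_call_rate minimum fraction of called chromosomes per site
#'   (default 0.8).
#' @return A `folded_sfs` object: list with `n_chromosomes` and `counts`
#'   (vector indexed by minor-allele count `1..floor(n/2)`);
#'   `sum(counts)` is the number of segregating sites S.
#' @export
folded_sfs <- function(tab, region = NULL, min_call_rate = 0.8) {
  n_chrom <- 2L * length(tab$samples)
  counts <- rep(0L, max(1L, n_chrom %/% 2L))
  sc <- .site_counts(.subset_table(tab, .sites_in_region(tab, region)))
  sc <- sc[sc$n >= min_call_rate * n_chrom & sc$n > 0, , drop = FALSE]
  minor <- pmin(sc$x, sc$n - sc$x)
  minor <- minor[minor > 0]
  if (length(minor)) {
    t <- tabulate(minor, nbins = length(counts))
    counts <- counts + t
  }
  structure(list(n_chromosomes = n_chrom, counts = counts),
            class = "folded_sfs")
}

#' Watterson's theta per site
#'
#' `theta_W = (S / a1(n)) / L_eff` with `a1(n) = sum_{i=1}^{n-1} 1/i`:
#' the segregating-site estimator of the population mutation rate
#' (4 Ne mu at mutation-drift equilibrium), normalized by the effective
#' number of sites so values are genomic proportions.
#'
#' @param S number of segregating sites.
#' @param n number of chromosomes (>= 2).
#' @param L_eff effective number of sites (callable bp).
#' @return per-site theta (numeric), `NA` when `L_eff` is 0.
#' @examples
#' watterson_theta(3, 4, 100)  # 0.01636364
#' @export
watterson_theta <- function(S, n, L_eff) {
  stopifnot(S >= 0, n >= 2)
  if (is.na(L_eff) || L_eff <= 0) return(NA_real_)
  (S / tajima_constants(n)$a1) / L_eff
}

# absolute (un-normalized) pairwise-difference sum over sites (internal):
# sum over sites of 2 x (n - x) / (n (n - 1)), x = alternate count,
# n = chromosomes called at the site
.pi_abs <- function(sc) {
  keep <- sc$n >= 2 & sc$x > 0 & sc$x < sc$n
  sc <- sc[keep, , drop = FALSE]
  if (!nrow(sc)) return(0)
  sum(2 * sc$x * (sc$n - sc$x) / (sc$n * (sc$n - 1)))
}

#' Nucleotide diversity per site
#'
#' Average number of pairwise nucleotide differences per site:
#' `sum_sites 2 x (n - x) / (n (n - 1)) / L_eff`, with the per-site called
#' chromosome number `n`.
#'
#' @inheritParams folded_sfs
#' @param L_eff effective number of sites.
#' @param min_call_rate minimum per-site call rate (default 0: keep all
#'   sites; windowed estimation applies its own threshold).
#' @return per-site pi (numeric), `NA` when `L_eff` is 0.
#' @export
nucleotide_diversity <- function(tab, region = NULL, L_eff,
                                 min_call_rate = 0) {
  if (is.na(L_eff) || L_eff <= 0) return(NA_real_)
  sc <- .site_counts(.subset_table(tab, .sites_in_region(tab, region)))
  n_chrom <- 2L * length(tab$samples)
  sc <- sc[sc$n >= min_call_rate * n_chrom, , drop = FALSE]
  .pi_abs(sc) / L_eff
}

#' Tajima's D
#'
#' The difference between the pairwise-difference estimator and the
#' segregating-sites estimator of theta, divided by the standard deviation
#' of that difference under mutation-drift equilibrium:
#' `D = (pi_abs - S/a1) / sqrt(e1 S + e2 S (S - 1))`.
#'
#' @param S number of segregating sites.
#' @param pi_abs absolute (un-normalized) pi for the same region.
#' @param n number of chromosomes.
#' @return D, or `NA` when `S = 0` (undefined; excluded from window means).
#' @export
tajimas_d <- function(S, pi_abs, n) {
  stopifnot(n >= 2)
  if (is.na(S) || S == 0) return(NA_real_)
  k <- tajima_constants(n)
  (pi_abs - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Per-window diversity statistics
#'
#' For each analysis window, computes the segregating-site count S,
#' per-site Watterson's theta and nucleotide diversity (normalized by the
#' window's `effective_sites`), and Tajima's D. Windows with
#' `effective_sites = 0` get `NA` statistics and are excluded from
#' population means.
#'
#' @param tab a [variant_table()].
#' @param windows window data frame from [make_windows()].
#' @param mask optional callable [interval_set()]; sites outside it are
#'   ignored.
#' @param min_call_rate per-site call-rate threshold (default 0.8).
#' @return `windows` with columns `n` (modal chromosomes), `S`, `theta_w`,
#'   `pi`, `pi_abs`, `tajimas_d` appended.
#' @export
window_stats <- function(tab, windows, mask = NULL, min_call_rate = 0.8) {
  n_chrom <- 2L * length(tab$samples)
  keep <- .sites_in_region(tab, mask)
  sc <- .site_counts(.subset_table(tab, keep))
  sc <- sc[sc$n >= min_call_rate * n_chrom & sc$n >= 2, , drop = FALSE]
  res <- windows
  res$n <- NA_integer_
  res$S <- NA_integer_
  res$theta_w <- NA_real_
  res$pi <- NA_real_
  res$pi_abs <- NA_real_
  res$tajimas_d <- NA_real_
  for (i in seq_len(nrow(windows))) {
    eff <- windows$effective_sites[i]
    if (is.na(eff) || eff <= 0) next
    w <- sc[sc$scaffold == windows$scaffold[i] &
              sc$pos >= windows$start[i] & sc$pos < windows$end[i], ,
            drop = FALSE]
    seg <- w$x > 0 & w$x < w$n
    S <- sum(seg)
    n_modal <- if (nrow(w)) as.integer(names(which.max(table(w$n))))
               else n_chrom
    pa <- .pi_abs(w)
    res$n[i] <- n_modal
    res$S[i] <- S
    res$theta_w[i] <- if (S == 0) 0 else watterson_theta(S, n_modal, eff)
    res$pi[i] <- pa / eff
    res$pi_abs[i] <- pa
    res$tajimas_d[i] <- if (n_modal >= 2) tajimas_d(S, pa, n_modal)
                        else NA_real_
  }
  res
}

#' Individual genome-wide heterozygosity
#'
#' The proportion of heterozygous sites in one sample: het count divided by
#' the number of callable sites. Missing genotypes are excluded from the
#' numerator; by default the denominator is the callable-mask length
#' (`callable_sites`).
#'
#' @param tab a [variant_table()].
#' @param sample sample identifier.
#' @param callable_sites callable bp for the denominator.
#' @param region optional [interval_set()] restricting the sites counted.
#' @return one-row data frame: `sample`, `het_sites`, `callable_sites`, `H`.
#' @export
individual_heterozygosity <- function(tab, sample, callable_sites,
                                      region = NULL) {
  if (!sample %in% tab$samples) stop("no such sample: ", sample)
  keep <- .sites_in_region(tab, region)
  g <- tab$geno[keep, sample]
  het <- sum(g == 1L, na.rm = TRUE)
  H <- if (is.na(callable_sites) || callable_sites <= 0) NA_real_
       else het / callable_sites
  data.frame(sample = sample, het_sites = het,
             callable_sites = callable_sites, H = H,
             stringsAsFactors = FALSE)
}

#' Population-level genomic diversity summary
#'
#' Arithmetic means over defined windows (theta_W, pi, D) and over
#' individuals (H), plus population ROH fractions when supplied: the
#' species-level profile used by the genetic categorization.
#'
#' @param window_stats output of [window_stats()].
#' @param het_estimates row-bound output of [individual_heterozygosity()].
#' @param froh_summaries optional `summary` data frame from [call_roh()].
#' @param label species or population label.
#' @param exclude_partial drop trailing partial windows from the means
#'   (default `FALSE`).
#' @return one-row data frame: `label`, `mean_theta_w`, `mean_pi`, `mean_H`,
#'   `mean_D`, `f100kb`, `f1mb`, `n_individuals`, `n_windows`.
#' @export
population_summary <- function(window_stats, het_estimates,
                               froh_summaries = NULL,
                               label = "population",
                               exclude_partial = FALSE) {
  w <- window_stats
  if (exclude_partial) w <- w[!w$partial, , drop = FALSE]
  defined <- !is.na(w$theta_w)
  if (!any(defined)) stop("no windows with defined statistics")
  w <- w[defined, , drop = FALSE]
  n_ind <- nrow(het_estimates)
  if (n_ind < 2) warning("population summary based on fewer than 2 individuals")
  fr <- if (is.null(froh_summaries)) list(f100kb = NA_real_, f1mb = NA_real_)
        else population_froh(froh_summaries)
  data.frame(label = label,
             mean_theta_w = mean(w$theta_w),
             mean_pi = mean(w$pi),
             mean_H = mean(het_estimates$H),
             mean_D = mean(w$tajimas_d, na.rm = TRUE),
             f100kb = fr$f100kb, f1mb = fr$f1mb,
             n_individuals = n_ind, n_windows = nrow(w),
             stringsAsFactors = FALSE)
}
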