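# Coalescent fixture generator: neutral genotype data at known theta, with
# optional injected autozygous tracts, so every estimator in the package
# can be validated against closed-form expectations.
#
# The simulator is a standard Kingman coalescent with infinite-sites
# mutation and no recombination within a window; windows are independent
# replicates. Under this model E[S] = theta * sum_{i=1}^{n-1} 1/i and the
# expected number of pairwise differences is theta.

#' Simulate one neutral coalescent window
#'
#' Draws a Kingman coalescent genealogy for `n_haplotypes` samples
#' (exponential waiting times with rate k(k-1)/2 while k lineages remain),
#' places mutations on branches as a Poisson process with rate `theta / 2`
#' per unit branch length, and assigns each mutation a unique, uniformly
#' drawn integer position in `[0, window_length)`.
#'
#' @param n_haplotypes number of sampled chromosomes (>= 2).
#' @param theta absolute (per-window) scaled mutation rate (> 0).
#' @param window_length window length in bp (default 50,000).
#' @param seed optional integer seed for reproducibility.
#' @return A `haplotype_sample`: list with `n_haplotypes`,
#'   `window_length`, and `sites`, a data frame of `position` plus a
#'   list-column `carriers` of derived-allele carrier index vectors
#'   (1-based haplotype indices).
#' @export
simulate_coalescent <- function(n_haplotypes, theta, window_length = 5e4,
                                seed = NULL) {
  stopifnot(n_haplotypes >= 2, theta > 0, window_length >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_haplotypes
  active_sets <- as.list(seq_len(n))
  birth <- rep(0, n)
  branch_sets <- vector("list", 2 * n - 2)
  branch_len <- numeric(2 * n - 2)
  nb <- 0L
  t <- 0
  while (length(active_sets) > 1) {
    k <- length(active_sets)
    t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
    pick <- sample.int(k, 2)
    for (p in pick) {
      nb <- nb + 1L
      branch_sets[[nb]] <- active_sets[[p]]
      branch_len[nb] <- t - birth[p]
    }
    merged <- c(active_sets[[pick[1]]], active_sets[[pick[2]]])
    active_sets <- c(active_sets[-pick], list(merged))
    birth <- c(birth[-pick], t)
  }
  total_len <- sum(branch_len)
  S <- stats::rpois(1, theta / 2 * total_len)
  S <- min(S, window_length)  # infinite-sites: at most one mutation per bp
  if (S > 0) {
    on_branch <- sample.int(nb, S, replace = TRUE, prob = branch_len)
    pos <- unique(floor(stats::runif(S, 0, window_length)))
    while (length(pos) < S) {
      pos <- unique(c(pos, floor(stats::runif(S - length(pos), 0,
                                              window_length))))
    }
    o <- order(pos)
    sites <- data.frame(position = pos[o])
    sites$carriers <- lapply(on_branch[o], function(b)
      sort(branch_sets[[b]]))
  } else {
    sites <- data.frame(position = numeric(0))
    sites$carriers <- list()
  }
  structure(list(n_haplotypes = n, window_length = window_length,
                 sites = sites),
            class = "haplotype_sample")
}

#' Pair haplotypes into diploid individuals
#'
#' Haplotypes (2i - 1, 2i) form individual i; per-site genotypes are the
#' derived-allele counts within each pair.
#'
#' @param hs a `haplotype_sample` from [simulate_coalescent()].
#' @param scaffold scaffold name for the resulting sites.
#' @param offset bp added to every position (used to lay windows end to
#'   end on one scaffold).
#' @param sample_prefix prefix for generated sample names.
#' @return A [variant_table()] with `n_haplotypes / 2` individuals.
#' @export
pair_diploids <- function(hs, scaffold = "sim_1", offset = 0,
                          sample_prefix = "ind") {
  n <- hs$n_haplotypes
  if (n %% 2 != 0) stop("haplotype count must be even to form diploids")
  n_ind <- n %/% 2
  samples <- sprintf("%s%02d", sample_prefix, seq_len(n_ind))
  m <- nrow(hs$sites)
  geno <- matrix(0L, m, n_ind, dimnames = list(NULL, samples))
  for (j in seq_len(m)) {
    carriers <- hs$sites$carriers[[j]]
    ind <- (carriers + 1L) %/% 2L
    counts <- tabulate(ind, nbins = n_ind)
    geno[j, ] <- counts
  }
  suppressWarnings(
    variant_table(rep(scaffold, m), hs$sites$position + offset, geno,
                  samples = samples))
}

#' Simulate a diploid population across replicate windows
#'
#' Simulates `n_windows` independent coalescent windows at absolute theta
#' `theta` each, pairs haplotypes into diploids, and lays the windows end
#' to end on one scaffold, giving a per-site theta of
#' `theta / window_length`.
#'
#' @param n_individuals diploid sample size.
#' @param theta absolute theta per window.
#' @param window_length window length in bp.
#' @param n_windows number of windows.
#' @param seed integer seed; output is deterministic given the seed.
#' @param scaffold scaffold name.
#' @return list of class `sim_population`: `table` (a [variant_table()]),
#'   `index` (a [genome_index()]), and the configuration fields.
#' @export
simulate_population <- function(n_individuals = 10, theta = 5,
                                window_length = 5e4, n_windows = 1,
                                seed = NULL, scaffold = "sim_1") {
  if (!is.null(seed)) set.seed(seed)
  tabs <- lapply(seq_len(n_windows), function(w) {
    hs <- simulate_coalescent(2 * n_individuals, theta, window_length)
    pair_diploids(hs, scaffold = scaffold,
                  offset = (w - 1) * window_length)
  })
  sites <- do.call(rbind, lapply(tabs, function(t) t$sites))
  geno <- do.call(rbind, lapply(tabs, function(t) t$geno))
  tab <- variant_table(sites$scaffold, sites$pos, geno,
                       samples = tabs[[1]]$samples)
  structure(list(table = tab,
                 index = genome_index(scaffold,
                                      n_windows * window_length),
                 n_individuals = n_individuals, theta = theta,
                 window_length = window_length, n_windows = n_windows,
                 seed = seed),
            class = "sim_population")
}

#' Inject autozygous tracts into a genotype table
#'
#' Within each tract, the named sample's heterozygous genotypes are
#' replaced by hom-ref, creating ground-truth ROH for validating the
#' caller; all other genotypes are untouched.
#'
#' @param tab a [variant_table()].
#' @param tracts data frame with columns `sample`, `scaffold`, `start`,
#'   `end` (0-based half-open). Overlapping tracts for one sample are an
#'   error.
#' @return The modified [variant_table()].
#' @export
inject_roh <- function(tab, tracts) {
  if (!nrow(tracts)) return(tab)
  stopifnot(all(c("sample", "scaffold", "start", "end") %in%
                  names(tracts)))
  for (key in split(seq_len(nrow(tracts)),
                    paste(tracts$sample, tracts$scaffold))) {
    tr <- tracts[key, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    if (nrow(tr) > 1 && any(tr$start[-1] < tr$end[-nrow(tr)])) {
      stop("overlapping tracts for sample ", tr$sample[1],
           " on ", tr$scaffold[1])
    }
  }
  geno <- tab$geno
  for (i in seq_len(nrow(tracts))) {
    smp <- tracts$sample[i]
    if (!smp %in% tab$samples) stop("no such sample: ", smp)
    rows <- tab$sites$scaffold == tracts$scaffold[i] &
      tab$sites$pos >= tracts$start[i] & tab$sites$pos < tracts$end[i]
    het <- rows & !is.na(geno[, smp]) & geno[, smp] == 1L
    geno[het, smp] <- 0L
  }
  structure(list(sites = tab$sites, geno = geno, samples = tab$samples),
            class = "variant_table")
}

#' Write a genotype table as a minimal VCF
#'
#' Emits a VCFv4.2 file with contig header lines from the genome index,
#' GT-only genotype columns, and placeholder A/T alleles (the estimators
#' depend only on genotype states, not on the nucleotides).
#'
#' @param tab a [variant_table()].
#' @param index a [genome_index()] covering the table's scaffolds.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(tab, index, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=gdassess-simulator",
              sprintf("##contig=<ID=%s,length=%d>", index$scaffold,
                      as.integer(index$length)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", tab$samples),
                    collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[tab$geno + 1L],
                   nrow = nrow(tab$geno))
  gt_str[is.na(gt_str)] <- "./."
  body <- if (nrow(tab$sites)) {
    paste(tab$sites$scaffold, format(tab$sites$pos + 1, scientific = FALSE,
                                     trim = TRUE),
          ".", "A", "T", ".", "PASS", ".", "GT",
          apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a complete test fixture to a directory
#'
#' Emits `fixture.vcf`, `genome_index.tsv`, an all-callable `callable.bed`,
#' and `truth.json` recording theta, seed and any injected tracts, so the
#' whole pipeline can be exercised from files alone.
#'
#' @param sim a `sim_population` from [simulate_population()] (its table
#'   possibly modified by [inject_roh()]).
#' @param dir output directory (created if needed).
#' @param tracts optional tract data frame recorded in the truth file.
#' @return named character vector of the files written.
#' @export
write_fixture <- function(sim, dir, tracts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(vcf = file.path(dir, "fixture.vcf"),
             index = file.path(dir, "genome_index.tsv"),
             callable = file.path(dir, "callable.bed"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$table, sim$index, files["vcf"])
  write_genome_index(sim$index, files["index"])
  write_bed(interval_set(sim$index$scaffold, rep(0, nrow(sim$index)),
                         sim$index$length), files["callable"])
  truth <- list(theta = sim$theta, window_length = sim$window_length,
                n_windows = sim$n_windows,
                n_individuals = sim$n_individuals,
                seed = sim$seed,
                tracts = if (is.null(tracts)) list() else tracts)
  jsonlite::write_json(truth, files["truth"], auto_unbox = TRUE,
                       digits = NA)
  files
}
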