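# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities from first principles (per-base
# boolean arrays, all-pairs differences, exhaustive path enumeration)
# rather than calling the implementation paths they check.

# per-base membership vector of an interval set on one scaffold
interval_membership <- function(a, scaffold, L) {
  v <- rep(FALSE, L)
  rows <- a[a$scaffold == scaffold, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    v[(rows$start[i] + 1):rows$end[i]] <- TRUE
  }
  v
}

# membership vector back to an interval_set on one scaffold
membership_to_intervals <- function(v, scaffold) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  if (!any(keep)) return(interval_set())
  interval_set(rep(scaffold, sum(keep)), starts[keep], ends[keep])
}

random_interval_set <- function(scaffold = "s", L = 2000, k = 5) {
  starts <- sort(sample(0:(L - 2), k))
  ends <- pmin(starts + sample(1:(L %/% 4), k, replace = TRUE), L)
  interval_set(rep(scaffold, k), starts, ends)
}

# all-pairs average per-site differences from a binary haplotype matrix
# (rows = sites, cols = haplotypes)
brute_pi_abs <- function(hap) {
  n <- ncol(hap)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(hap[, i] != hap[, j])
  }
  tot / choose(n, 2)
}

# genotype table from a haplotype matrix (haplotypes 2i-1, 2i pair up)
geno_from_haplotypes <- function(hap, scaffold = "s",
                                 pos = seq_len(nrow(hap)) * 10) {
  n_ind <- ncol(hap) %/% 2
  geno <- sapply(seq_len(n_ind), function(i) {
    hap[, 2 * i - 1] + hap[, 2 * i]
  })
  geno <- matrix(as.integer(geno), nrow = nrow(hap))
  colnames(geno) <- paste0("ind", seq_len(n_ind))
  suppressWarnings(variant_table(rep(scaffold, nrow(hap)), pos, geno))
}

# log probability of one state path, written independently of the
# package's Viterbi (its own emission and transition arithmetic)
roh_path_logprob <- function(path, obs, positions, params,
                             het_freq = NULL) {
  m <- length(obs)
  p_hw <- if (params$use_site_frequencies && !is.null(het_freq)) {
    pmin(pmax(het_freq, 1e-4), 0.5)
  } else rep(params$p_het_hw, m)
  emis <- function(state, t) {
    p_het <- if (state == "AZ") params$p_het_in_roh else p_hw[t]
    switch(obs[t], het = log(p_het), hom = log(1 - p_het), missing = 0)
  }
  g <- diff(positions)
  p_stay <- (1 - params$transition_per_bp)^g
  lp <- log(0.5) + emis(path[1], 1)
  for (t in seq_len(m)[-1]) {
    lp <- lp + log(if (path[t] == path[t - 1]) p_stay[t - 1]
                   else 1 - p_stay[t - 1]) + emis(path[t], t)
  }
  lp
}

# exhaustive maximum-probability path over {AZ, HW}. Returns the best path
# with attributes "logp" (its log probability) and "unique" (whether the
# maximum is attained by exactly one path; when FALSE, any argmax path is
# a correct decoding and only the score can be compared).
brute_force_roh_path <- function(obs, positions, params, het_freq = NULL) {
  m <- length(obs)
  codes <- 0:(2^m - 1)
  paths <- lapply(codes, function(code) {
    c("AZ", "HW")[as.integer(intToBits(code))[1:m] + 1L]
  })
  lp <- vapply(paths, roh_path_logprob, 0, obs = obs,
               positions = positions, params = params, het_freq = het_freq)
  best <- which.max(lp)
  out <- paths[[best]]
  attr(out, "logp") <- lp[best]
  attr(out, "unique") <- sum(lp > lp[best] - 1e-9) == 1
  out
}

# minimal VCF writer used to hand-build parser fixtures
write_test_vcf <- function(records, samples = c("s1", "s2"),
                           contig = "c1", contig_len = 1e6) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records), f)
  f
}
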