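# Genome index, interval sets, analysis windows and genotype input.
#
# All coordinates are 0-based half-open (BED convention). VCF positions are
# converted on read; IRanges (1-based closed) is used internally for the
# interval arithmetic and never exposed.

#' Genome index: scaffold names and lengths
#'
#' @param scaffold character vector of unique scaffold identifiers.
#' @param length integer vector of scaffold lengths in bp (> 0).
#' @return A `genome_index` data frame with columns `scaffold`, `length`.
#' @examples
#' genome_index(c("s1", "s2"), c(2e6, 5e4))
#' @export
genome_index <- function(scaffold, length) {
  scaffold <- as.character(scaffold)
  length <- as.numeric(length)
  if (anyDuplicated(scaffold)) stop("duplicated scaffold identifiers")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("scaffold lengths must be positive")
  }
  structure(data.frame(scaffold = scaffold, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_index", "data.frame"))
}

#' Read a two-column genome index file (scaffold, length)
#'
#' @param path path to a whitespace-delimited file, e.g. the first two
#'   columns of a samtools `.fai` index.
#' @return A [genome_index()].
#' @export
read_genome_index <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  genome_index(df[[1]], df[[2]])
}

#' Write a genome index file
#' @param index a [genome_index()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_index <- function(index, path) {
  utils::write.table(index[, c("scaffold", "length")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Drop scaffolds shorter than a minimum length
#'
#' Mirrors the usual assembly filter: scaffolds under 100 kb (including
#' mitochondrial sequences) are removed before diversity estimation. The
#' boundary is inclusive: a scaffold of exactly `min_len` is retained.
#'
#' @param index a [genome_index()].
#' @param min_len minimum scaffold length in bp (default 100,000).
#' @return The filtered [genome_index()], input order preserved.
#' @export
filter_scaffolds <- function(index, min_len = 1e5) {
  stopifnot(min_len > 0)
  out <- index[index$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("genome_index", "data.frame"))
}

## ---- interval sets ----------------------------------------------------

#' Normalized set of genomic intervals
#'
#' Intervals are 0-based half-open, sorted by (scaffold, start), with
#' overlapping or abutting intervals merged, so each set is a canonical
#' representation of a subset of the genome (a mask, a window set, ROH
#' segments, ...).
#'
#' @param scaffold character vector.
#' @param start,end numeric vectors, `start < end`, 0-based half-open.
#' @return An `interval_set` data frame with columns `scaffold`, `start`,
#'   `end`.
#' @examples
#' interval_set("s1", c(0, 500), c(1000, 1500))  # merged to [0,1500)
#' @export
interval_set <- function(scaffold = character(), start = numeric(),
                         end = numeric()) {
  scaffold <- as.character(scaffold)
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(length(scaffold) == length(start), length(start) == length(end))
  if (any(start < 0) || any(start >= end)) {
    stop("intervals must satisfy 0 <= start < end")
  }
  pieces <- lapply(split(seq_along(scaffold), scaffold), function(i) {
    ir <- IRanges::reduce(IRanges::IRanges(start[i] + 1, end[i]))
    data.frame(scaffold = scaffold[i[1]],
               start = IRanges::start(ir) - 1,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(scaffold = character(), start = numeric(), end = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("interval_set", "data.frame"))
}

#' Coerce a data frame with scaffold/start/end columns to an interval set
#' @param df data frame with `scaffold`, `start`, `end` columns.
#' @return A normalized [interval_set()].
#' @export
as_interval_set <- function(df) {
  interval_set(df$scaffold, df$start, df$end)
}

# split an interval_set into a named list of IRanges, one per scaffold
.iranges_by_scaffold <- function(a) {
  lapply(split(seq_len(nrow(a)), a$scaffold), function(i) {
    IRanges::IRanges(a$start[i] + 1, a$end[i])
  })
}

.set_from_iranges <- function(irl) {
  keep <- vapply(irl, length, 1L) > 0
  irl <- irl[keep]
  if (!length(irl)) return(interval_set())
  interval_set(rep(names(irl), vapply(irl, length, 1L)),
               unlist(lapply(irl, function(ir) IRanges::start(ir) - 1)),
               unlist(lapply(irl, IRanges::end)))
}

#' Total width of an interval set in bp
#' @param a an [interval_set()].
#' @return numeric, sum of interval lengths.
#' @export
interval_width <- function(a) {
  if (!nrow(a)) return(0)
  sum(a$end - a$start)
}

#' Intersect two interval sets
#'
#' Used to combine callability masks: e.g. non-repeat regions, regions of
#' mappability 1, and length-filtered scaffolds.
#'
#' @param a,b normalized [interval_set()]s.
#' @return The normalized intersection.
#' @export
intersect_intervals <- function(a, b) {
  ia <- .iranges_by_scaffold(a)
  ib <- .iranges_by_scaffold(b)
  common <- intersect(names(ia), names(ib))
  .set_from_iranges(setNames(
    lapply(common, function(s) IRanges::intersect(ia[[s]], ib[[s]])),
    common))
}

#' Complement an interval set within the genome
#'
#' Per-scaffold set complement within `[0, length)` for every scaffold in
#' `index` (the bedtools-complement operation used to turn a repeat
#' annotation into a non-repeat mask).
#'
#' @param a an [interval_set()] confined to scaffolds in `index`.
#' @param index a [genome_index()].
#' @return The normalized complement.
#' @export
complement_intervals <- function(a, index) {
  bad <- setdiff(unique(a$scaffold), index$scaffold)
  if (length(bad)) stop("intervals on scaffolds absent from index: ",
                        paste(bad, collapse = ", "))
  len <- setNames(index$length, index$scaffold)
  if (nrow(a) && any(a$end > len[a$scaffold])) {
    stop("interval extends beyond scaffold length")
  }
  ia <- .iranges_by_scaffold(a)
  out <- lapply(index$scaffold, function(s) {
    ir <- if (s %in% names(ia)) ia[[s]] else IRanges::IRanges()
    IRanges::gaps(ir, start = 1, end = len[[s]])
  })
  .set_from_iranges(setNames(out, index$scaffold))
}

#' Read a 3-column BED file as an interval set
#' @param path path to an uncompressed BED file.
#' @return An [interval_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (!length(gr)) return(interval_set())
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1,
               GenomicRanges::end(gr))
}

#' Write an interval set as 3-column BED
#' @param a an [interval_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(a, path) {
  gr <- GenomicRanges::GRanges(a$scaffold,
                               IRanges::IRanges(a$start + 1, a$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

## ---- windows ----------------------------------------------------------

#' Tile scaffolds into non-overlapping analysis windows
#'
#' Tiles each scaffold left to right with `window_size` bp windows; the
#' trailing partial window is kept and flagged. `effective_sites` is the
#' number of callable bp in the window according to `mask` (the whole
#' window when `mask` is `NULL`), and is the per-site denominator used by
#' the diversity estimators.
#'
#' @param index a [genome_index()] (already scaffold-length filtered).
#' @param window_size window length in bp (default 50,000).
#' @param mask optional callable-site [interval_set()].
#' @return data frame with columns `scaffold`, `start`, `end`, `partial`,
#'   `effective_sites`.
#' @export
make_windows <- function(index, window_size = 5e4, mask = NULL) {
  stopifnot(window_size > 0)
  mask_ir <- if (is.null(mask)) NULL else .iranges_by_scaffold(mask)
  rows <- lapply(seq_len(nrow(index)), function(i) {
    s <- index$scaffold[i]
    len <- index$length[i]
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    eff <- ends - starts
    if (!is.null(mask_ir)) {
      if (s %in% names(mask_ir)) {
        cov <- IRanges::coverage(mask_ir[[s]], width = len)
        eff <- as.numeric(sum(IRanges::Views(cov,
          IRanges::IRanges(starts + 1, ends))))
      } else {
        eff <- rep(0, length(starts))
      }
    }
    data.frame(scaffold = s, start = starts, end = ends,
               partial = (ends - starts) < window_size,
               effective_sites = eff, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- genotype tables --------------------------------------------------

#' Per-site diploid genotypes for one population
#'
#' Genotypes are coded as the count of alternate alleles: 0 (hom-ref),
#' 1 (het), 2 (hom-alt), `NA` (missing). Positions are 0-based and must be
#' strictly increasing within scaffold; only biallelic sites are stored.
#'
#' @param scaffold,pos site coordinates (0-based).
#' @param geno integer matrix, sites x samples, values in {0, 1, 2, NA}.
#' @param samples sample identifiers (defaults to `colnames(geno)`).
#' @return A `variant_table` object.
#' @export
variant_table <- function(scaffold, pos, geno, samples = colnames(geno)) {
  geno <- as.matrix(geno)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(geno)))
  stopifnot(length(scaffold) == nrow(geno), length(pos) == nrow(geno),
            length(samples) == ncol(geno))
  if (!all(geno %in% c(0L, 1L, 2L) | is.na(geno))) {
    stop("genotypes must be 0, 1, 2 or NA")
  }
  o <- order(scaffold, pos)
  scaffold <- as.character(scaffold)[o]
  pos <- as.numeric(pos)[o]
  geno <- geno[o, , drop = FALSE]
  if (any(unlist(tapply(pos, scaffold, function(p) diff(p) <= 0)))) {
    stop("positions must be strictly increasing within scaffold")
  }
  if (ncol(geno) < 2 || ncol(geno) > 25) {
    warning("sample count ", ncol(geno), " outside the recommended 2-25 range")
  }
  mode(geno) <- "integer"
  dimnames(geno) <- list(NULL, samples)
  structure(list(sites = data.frame(scaffold = scaffold, pos = pos,
                                    stringsAsFactors = FALSE),
                 geno = geno, samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "sites,",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Number of sites in a variant table
#' @param tab a [variant_table()].
#' @return integer site count.
#' @export
n_sites <- function(tab) nrow(tab$sites)

#' Read diploid genotypes from a VCF file
#'
#' Retains biallelic SNP records only; multi-allelic or non-SNP records are
#' skipped with a logged count. Genotypes are mapped to the 4-state alphabet
#' (hom-ref / het / hom-alt / missing); phase is ignored and half-calls are
#' treated as missing.
#'
#' @param path path to a VCF file with GT fields.
#' @param samples optional character vector restricting (and ordering) the
#'   samples; an absent sample is an error naming it.
#' @return A [variant_table()].
#' @export
read_genotype_table <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  all_samples <- colnames(vcf@gt)[-1]
  if (!is.null(samples)) {
    missing <- setdiff(samples, all_samples)
    if (length(missing)) {
      stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
    }
  } else {
    samples <- all_samples
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(vcf@fix)
  if (n == 0) {
    return(variant_table(character(), numeric(),
                         matrix(integer(), 0, length(samples)),
                         samples = samples))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  if (any(!snp)) {
    message("read_genotype_table: skipped ", sum(!snp),
            " non-biallelic or non-SNP record(s)")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n,
                                     dimnames = list(NULL, all_samples))
  gt <- gt[snp, samples, drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt %in% c("0/0")] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% c("1/1")] <- 2L
  variant_table(fix[snp, "CHROM"], as.numeric(fix[snp, "POS"]) - 1,
                code, samples = samples)
}

# subset rows of a variant table (internal)
.subset_table <- function(tab, keep) {
  structure(list(sites = tab$sites[keep, , drop = FALSE],
                 geno = tab$geno[keep, , drop = FALSE],
                 samples = tab$samples),
            class = "variant_table")
}

# logical vector: is each site inside the interval set? (internal)
.sites_in_region <- function(tab, region) {
  if (is.null(region)) return(rep(TRUE, n_sites(tab)))
  keep <- rep(FALSE, n_sites(tab))
  ir <- .iranges_by_scaffold(region)
  for (s in unique(tab$sites$scaffold)) {
    i <- which(tab$sites$scaffold == s)
    if (s %in% names(ir)) {
      keep[i] <- IRanges::overlapsAny(
        IRanges::IRanges(tab$sites$pos[i] + 1, width = 1), ir[[s]])
    }
  }
  keep
}

#' Build a callable-site mask from repeat and mappability inputs
#'
#' Convenience composition: length-filter the genome, complement the repeat
#' intervals, and intersect with the mappability intervals, yielding the
#' callable mask used as denominator for per-site diversity.
#'
#' @param index a [genome_index()].
#' @param repeats repeat annotation [interval_set()] (masked out).
#' @param mappability optional [interval_set()] of uniquely mappable
#'   regions (kept).
#' @param min_scaffold minimum scaffold length (default 100 kb).
#' @return list with `index` (filtered) and `callable` (the mask).
#' @export
callable_mask <- function(index, repeats = interval_set(),
                          mappability = NULL, min_scaffold = 1e5) {
  idx <- filter_scaffolds(index, min_scaffold)
  keep_rep <- repeats[repeats$scaffold %in% idx$scaffold, , drop = FALSE]
  mask <- complement_intervals(as_interval_set(keep_rep), idx)
  if (!is.null(mappability)) {
    mask <- intersect_intervals(mask, mappability)
  }
  list(index = idx, callable = mask)
}
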