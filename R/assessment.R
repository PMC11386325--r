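# Heterozygosity-loss projection under drift and the genetic Red List
# decision tree.
#
# The projection is the classical expected loss of heterozygosity in an
# ideal population of effective size Ne: H_T = H_O (1 - 1/(2 Ne))^T, with T
# the number of generations in the assessment horizon (100 years by
# default, matching Green Status time frames). Categories follow the
# decision tree: the H_T:H_O ratio first, Ne floors as a safeguard that can
# only worsen a category, and a relative-H_O comparison against already
# threatened relatives (same taxonomic Order, Family as fallback) for
# species whose Ne cannot be derived, whose generation time is long, or
# that otherwise come out Least Concern.

#' Category thresholds for the genetic decision tree
#'
#' The H_T:H_O ratio bounds and Ne floors. The VU bound (0.975) and the
#' Ne < 1000 floor come from the tree itself; the CR/EN ratio split at 0.90
#' and the EN:500 / CR:100 floors are package defaults (the EN floor echoes
#' the CBD Ne > 500 indicator) and are recorded in the provenance of every
#' assignment they fire for.
#'
#' @param ratio_cr,ratio_en,ratio_vu H_T:H_O bounds (category assigned when
#'   the ratio is <= the bound); must be strictly increasing and < 1.
#' @param ne_vu,ne_en,ne_cr Ne floors (category at least VU/EN/CR when Ne
#'   is below the floor); strictly decreasing.
#' @param long_generation_years generation time above which the ratio route
#'   is considered too slow and the relative-H_O route is used instead
#'   (default 15 y).
#' @return list of class `category_thresholds`.
#' @export
category_thresholds <- function(ratio_cr = 0.90, ratio_en = 0.95,
                                ratio_vu = 0.975,
                                ne_vu = 1000, ne_en = 500, ne_cr = 100,
                                long_generation_years = 15) {
  stopifnot(ratio_cr < ratio_en, ratio_en < ratio_vu, ratio_vu < 1,
            ne_vu > ne_en, ne_en > ne_cr, long_generation_years > 0)
  structure(list(ratio_cr = ratio_cr, ratio_en = ratio_en,
                 ratio_vu = ratio_vu, ne_vu = ne_vu, ne_en = ne_en,
                 ne_cr = ne_cr,
                 long_generation_years = long_generation_years),
            class = "category_thresholds")
}

#' Number of generations in the assessment horizon
#'
#' `T = horizon_years / generation_time`, real-valued: 50 for a 2-year
#' generation time, 5 for a 20-year generation time over 100 years.
#'
#' @param generation_time_years generation time t in years (> 0).
#' @param horizon_years assessment horizon (default 100).
#' @return T (numeric).
#' @export
generations_in_horizon <- function(generation_time_years,
                                   horizon_years = 100) {
  if (is.na(generation_time_years) || generation_time_years <= 0) {
    stop("generation time must be positive")
  }
  horizon_years / generation_time_years
}

#' Project heterozygosity loss under drift
#'
#' `H_T = H_O (1 - 1/(2 Ne))^T`, evaluated in log space for numerical
#' safety at large Ne.
#'
#' @param H_O observed heterozygosity (>= 0).
#' @param Ne effective population size (> 0.5).
#' @param T number of generations (>= 0), from [generations_in_horizon()].
#' @return list: `H_O`, `Ne`, `T`, `H_T`, and `ratio` (= H_T / H_O).
#' @examples
#' project_heterozygosity(0.00041, 651.7, 100 / 6)$ratio  # ~0.987
#' @export
project_heterozygosity <- function(H_O, Ne, T) {
  stopifnot(H_O >= 0, T >= 0)
  if (is.na(Ne) || Ne <= 0.5) stop("Ne must exceed 0.5")
  ratio <- exp(T * log1p(-1 / (2 * Ne)))
  list(H_O = H_O, Ne = Ne, T = T, H_T = H_O * ratio, ratio = ratio)
}

#' Effective size from census size
#' @param Nc census population size (> 0).
#' @param ratio Ne/Nc ratio in (0, 1], e.g. 0.10 (strict) or 1.00 (lenient).
#' @return Ne = Nc * ratio.
#' @export
ne_from_nc <- function(Nc, ratio) {
  stopifnot(Nc > 0, ratio > 0, ratio <= 1)
  Nc * ratio
}

#' Effective size from Watterson's theta
#'
#' Inverts theta_W = 4 Ne mu at mutation-drift equilibrium.
#'
#' @param theta_w_per_site per-site Watterson's theta (>= 0).
#' @param mu per-site per-generation mutation rate (> 0).
#' @return Ne = theta_W / (4 mu).
#' @export
ne_from_theta <- function(theta_w_per_site, mu) {
  stopifnot(theta_w_per_site >= 0)
  if (is.na(mu) || mu <= 0) stop("mutation rate must be positive")
  theta_w_per_site / (4 * mu)
}

#' Species profile for categorization
#'
#' Collects a taxon's inputs for the decision tree. Any of `Ne`,
#' (`Nc`, `ne_nc_ratio`), or (`theta_w`, `mu`) can supply the effective
#' size; when none does, only the relative-H_O route applies.
#'
#' @param label taxon label.
#' @param H_O observed heterozygosity.
#' @param generation_time_years generation time in years.
#' @param taxon_order,taxon_family taxonomy used by the relative-H_O rule.
#' @param Ne,Nc,ne_nc_ratio,theta_w,mu optional Ne inputs.
#' @return list of class `species_profile`.
#' @export
species_profile <- function(label, H_O, generation_time_years,
                            taxon_order = NA_character_,
                            taxon_family = NA_character_,
                            Ne = NA_real_, Nc = NA_real_,
                            ne_nc_ratio = NA_real_,
                            theta_w = NA_real_, mu = NA_real_) {
  structure(list(label = label, H_O = H_O,
                 generation_time_years = generation_time_years,
                 taxon_order = taxon_order, taxon_family = taxon_family,
                 Ne = Ne, Nc = Nc, ne_nc_ratio = ne_nc_ratio,
                 theta_w = theta_w, mu = mu),
            class = "species_profile")
}

# derive Ne from whichever inputs are present (internal); NA when none
.derive_ne <- function(p) {
  if (!is.na(p$Ne)) return(p$Ne)
  if (!is.na(p$Nc) && !is.na(p$ne_nc_ratio)) {
    return(ne_from_nc(p$Nc, p$ne_nc_ratio))
  }
  if (!is.na(p$theta_w) && !is.na(p$mu)) {
    return(ne_from_theta(p$theta_w, p$mu))
  }
  NA_real_
}

#' Relative-H_O threshold from threatened relatives
#'
#' The maximum observed heterozygosity among reference taxa already in a
#' threatened genetic category (VU, EN, CR) in the same taxonomic Order,
#' falling back to Family when the Order has none. The maximum (rather
#' than a mean or median) only increases as references accrue, which keeps
#' the threshold stable.
#'
#' @param reference data frame with columns `H_O`, `category`, and
#'   `taxon_order` / `taxon_family` (taxonomy columns optional when
#'   `taxon_order` is `NULL`).
#' @param taxon_order,taxon_family taxonomy of the species being assessed;
#'   `NULL` to use the whole reference.
#' @return the maximum threatened H_O, or `NA` when no threatened
#'   reference exists at either level.
#' @export
relative_ho_threshold <- function(reference, taxon_order = NULL,
                                  taxon_family = NULL) {
  thr <- reference[reference$category %in% c("VU", "EN", "CR"), ,
                   drop = FALSE]
  if (!nrow(thr)) return(NA_real_)
  if (!is.null(taxon_order)) {
    sel <- thr[!is.na(thr$taxon_order) & thr$taxon_order == taxon_order, ,
               drop = FALSE]
    if (!nrow(sel) && !is.null(taxon_family)) {
      sel <- thr[!is.na(thr$taxon_family) &
                   thr$taxon_family == taxon_family, , drop = FALSE]
    }
    thr <- sel
  }
  if (!nrow(thr)) return(NA_real_)
  max(thr$H_O)
}

.category_rank <- c(LC = 1, NT = 2, VU = 3, EN = 4, CR = 5)

#' Assign a genetic conservation category
#'
#' Applies the decision tree to one species: (1) when Ne is derivable and
#' the generation time is not long, categorize by the projected H_T:H_O
#' ratio (<= 0.90 CR, <= 0.95 EN, <= 0.975 VU); (2) Ne floors may only
#' worsen the result (Ne < 1000 at least VU, < 500 EN, < 100 CR); (3) the
#' relative-H_O comparison applies when Ne is underivable, when the
#' generation time exceeds the configured bound, or when the tree yields
#' LC and a reference is available: H_O below the threatened maximum of
#' relatives gives a Threatened determination (conventionally reported as
#' VU); (4) otherwise LC. Exactly one rule is recorded as provenance.
#'
#' @param profile a [species_profile()].
#' @param thresholds [category_thresholds()].
#' @param reference optional reference table for
#'   [relative_ho_threshold()].
#' @param horizon_years assessment horizon (default 100).
#' @return list of class `genetic_category`: `label`, `category` (one of
#'   LC, VU, EN, CR, Threatened), `provenance`, `Ne`, `ratio`.
#' @export
assign_genetic_category <- function(profile,
                                    thresholds = category_thresholds(),
                                    reference = NULL,
                                    horizon_years = 100) {
  Ne <- .derive_ne(profile)
  long_gen <- !is.na(profile$generation_time_years) &&
    profile$generation_time_years > thresholds$long_generation_years
  ratio <- NA_real_
  category <- NA_character_
  provenance <- NA_character_

  if (!is.na(Ne) && !long_gen) {
    T <- generations_in_horizon(profile$generation_time_years,
                                horizon_years)
    ratio <- project_heterozygosity(max(profile$H_O, 0), Ne, T)$ratio
    if (ratio <= thresholds$ratio_cr) {
      category <- "CR"
      provenance <- sprintf("H_T:H_O = %.4f <= %.3f", ratio,
                            thresholds$ratio_cr)
    } else if (ratio <= thresholds$ratio_en) {
      category <- "EN"
      provenance <- sprintf("H_T:H_O = %.4f <= %.3f", ratio,
                            thresholds$ratio_en)
    } else if (ratio <= thresholds$ratio_vu) {
      category <- "VU"
      provenance <- sprintf("H_T:H_O = %.4f <= %.3f", ratio,
                            thresholds$ratio_vu)
    } else {
      category <- "LC"
      provenance <- sprintf("H_T:H_O = %.4f above all ratio thresholds",
                            ratio)
    }
    # Ne floors: a safeguard that can only worsen the category
    floor_cat <- if (Ne < thresholds$ne_cr) "CR"
                 else if (Ne < thresholds$ne_en) "EN"
                 else if (Ne < thresholds$ne_vu) "VU"
                 else NA_character_
    if (!is.na(floor_cat) &&
        .category_rank[floor_cat] > .category_rank[category]) {
      category <- floor_cat
      floor_val <- switch(floor_cat, VU = thresholds$ne_vu,
                          EN = thresholds$ne_en, CR = thresholds$ne_cr)
      provenance <- sprintf("Ne = %.1f < %g floor", Ne, floor_val)
    }
  }

  # relative-H_O route: no Ne, long generation time, or tree says LC
  relative_applies <- is.na(Ne) || long_gen ||
    (identical(category, "LC") && !is.null(reference))
  if (relative_applies) {
    if (is.null(reference)) {
      if (is.na(category)) {
        return(structure(list(label = profile$label,
                              category = NA_character_,
                              provenance = paste("no route applicable:",
                                "Ne underivable or generation time long,",
                                "and no reference supplied"),
                              Ne = Ne, ratio = ratio),
                         class = "genetic_category"))
      }
    } else {
      ho_max <- relative_ho_threshold(
        reference,
        taxon_order = if (is.na(profile$taxon_order)) NULL
                      else profile$taxon_order,
        taxon_family = if (is.na(profile$taxon_family)) NULL
                       else profile$taxon_family)
      if (!is.na(ho_max) && profile$H_O < ho_max) {
        category <- "Threatened"
        provenance <- sprintf(
          "relative H_O rule: H_O = %g < threatened maximum %g (reported as VU)",
          profile$H_O, ho_max)
      } else if (is.na(category)) {
        category <- "LC"
        provenance <- "relative H_O rule: H_O not below threatened maximum"
      }
    }
  }

  structure(list(label = profile$label, category = category,
                 provenance = provenance, Ne = Ne, ratio = ratio),
            class = "genetic_category")
}

#' Collapse categories to Threatened / Non-Threatened
#'
#' VU, EN, CR, and relative-H_O Threatened determinations collapse to
#' `"Threatened"`; LC and NT to `"Non-Threatened"`.
#'
#' @param category character vector of categories.
#' @return character vector.
#' @export
collapse_binary <- function(category) {
  out <- rep(NA_character_, length(category))
  out[category %in% c("VU", "EN", "CR", "Threatened")] <- "Threatened"
  out[category %in% c("LC", "NT")] <- "Non-Threatened"
  out
}

#' Map a genetic category to a Red List code
#'
#' Relative-H_O Threatened determinations are reported as VU by
#' convention; other categories pass through.
#'
#' @param category character vector.
#' @return character vector of Red List codes.
#' @export
as_redlist <- function(category) {
  ifelse(category == "Threatened", "VU", category)
}

#' Categorize a table of species
#'
#' Two-pass application of the decision tree to a species table: the first
#' pass assigns tree categories (ratio + Ne floors) to every species; the
#' second pass builds the threatened reference per taxonomic Order/Family
#' from pass-one results and applies the relative-H_O rule to species that
#' were LC or unresolved.
#'
#' @param species data frame with columns `label`, `H_O`,
#'   `generation_time_years`, and optionally `taxon_order`,
#'   `taxon_family`, `Ne`, `Nc`, `theta_w`, `mu`.
#' @param ne_nc_ratio Ne/Nc ratio applied to every species with `Nc`
#'   (default 0.10).
#' @param thresholds [category_thresholds()].
#' @param horizon_years assessment horizon.
#' @return `species` with `Ne`, `ratio`, `category`, `redlist`, `binary`
#'   and `provenance` columns appended.
#' @export
genetic_categories <- function(species, ne_nc_ratio = 0.10,
                               thresholds = category_thresholds(),
                               horizon_years = 100) {
  col_or_na <- function(nm) {
    if (nm %in% names(species)) species[[nm]] else rep(NA, nrow(species))
  }
  profiles <- lapply(seq_len(nrow(species)), function(i) {
    species_profile(label = species$label[i], H_O = species$H_O[i],
                    generation_time_years = species$generation_time_years[i],
                    taxon_order = as.character(col_or_na("taxon_order")[i]),
                    taxon_family = as.character(col_or_na("taxon_family")[i]),
                    Ne = as.numeric(col_or_na("Ne")[i]),
                    Nc = as.numeric(col_or_na("Nc")[i]),
                    ne_nc_ratio = ne_nc_ratio,
                    theta_w = as.numeric(col_or_na("theta_w")[i]),
                    mu = as.numeric(col_or_na("mu")[i]))
  })
  pass1 <- lapply(profiles, assign_genetic_category,
                  thresholds = thresholds, reference = NULL,
                  horizon_years = horizon_years)
  reference <- data.frame(
    label = vapply(pass1, `[[`, "", "label"),
    H_O = species$H_O,
    category = vapply(pass1, function(x)
      ifelse(is.na(x$category), "NA", x$category), ""),
    taxon_order = as.character(col_or_na("taxon_order")),
    taxon_family = as.character(col_or_na("taxon_family")),
    stringsAsFactors = FALSE)
  out <- lapply(seq_along(profiles), function(i) {
    p1 <- pass1[[i]]
    if (!is.na(p1$category) && p1$category %in% c("VU", "EN", "CR")) {
      return(p1)
    }
    assign_genetic_category(profiles[[i]], thresholds = thresholds,
                            reference = reference,
                            horizon_years = horizon_years)
  })
  species$Ne <- vapply(out, function(x) x$Ne %||% NA_real_, 0)
  species$ratio <- vapply(out, function(x) x$ratio %||% NA_real_, 0)
  species$category <- vapply(out, `[[`, "", "category")
  species$redlist <- as_redlist(species$category)
  species$binary <- collapse_binary(species$category)
  species$provenance <- vapply(out, `[[`, "", "provenance")
  species
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
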