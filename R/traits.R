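#' Left-ventricular dilation (LVD) after MI
#'
#' Percent increase in LV diastolic volume after MI relative to the
#' pre-infarction volume:
#' `LVD = vol_after / vol_before * 100 - 100`.
#' Positive values indicate dilation.
#'
#' @param lv_vol_d_before,lv_vol_d_after LV diastolic volumes (microlitres),
#'   both strictly positive. Vectorized.
#' @return LVD in percent.
#' @export
compute_lvd <- function(lv_vol_d_before, lv_vol_d_after) {
  if (any(lv_vol_d_before <= 0) || any(lv_vol_d_after <= 0))
    stop("LV volumes must be positive")
  lv_vol_d_after / lv_vol_d_before * 100 - 100
}

#' Reduction in ejection fraction (delta-EF) after MI
#'
#' Percent change in EF relative to the post-MI value:
#' `delta_EF = (EF_before - EF_after) / EF_after * 100`.
#' Positive values indicate a reduction in EF.
#'
#' @param ef_before,ef_after Ejection fractions in percent; `ef_after > 0`.
#'   Vectorized.
#' @return delta-EF in percent.
#' @export
compute_delta_ef <- function(ef_before, ef_after) {
  if (any(ef_after <= 0)) stop("ef_after must be positive")
  (ef_before - ef_after) / ef_after * 100
}

#' Apply the cohort inclusion filters
#'
#' Removes animals whose infarct size does not exceed `mi_size_threshold`
#' percent of the LV (small infarcts do not produce significant EF reduction
#' or remodeling, so they are excluded from post-MI analyses). `MI_size` is
#' read from the post-MI rows of the echo records; an animal with a missing
#' `MI_size` is dropped with a warning, and it is an error if no animal in
#' the cohort has a recorded infarct size. Strains whose mean included
#' infarct size is far from the ~40% comparability target are flagged with a
#' warning but retained.
#'
#' @param records Echo records data.frame (see [simulate_cohort_traits()]).
#' @param survival Optional survival log; filtered to the same animals.
#' @param mi_size_threshold Inclusion threshold in percent of LV, in (0, 100).
#' @param comparability_target,comparability_tol Mean infarct-size screen
#'   (warning only).
#' @return List with `records`, `survival` (or `NULL`), and `removed`
#'   (data.frame of per-strain counts of excluded animals).
#' @export
apply_inclusion_filters <- function(records, survival = NULL,
                                    mi_size_threshold = 30,
                                    comparability_target = 40,
                                    comparability_tol = 15) {
  if (mi_size_threshold <= 0 || mi_size_threshold >= 100)
    stop("mi_size_threshold must be in (0, 100)")
  post <- records[records$timepoint == "after", ]
  if (all(is.na(post$MI_size)))
    stop("no animal has a recorded MI_size; affected animals: ",
         paste(post$animal_id, collapse = ", "))
  if (anyNA(post$MI_size))
    warning("animals with missing MI_size excluded: ",
            paste(post$animal_id[is.na(post$MI_size)], collapse = ", "))
  keep <- post$animal_id[!is.na(post$MI_size) & post$MI_size > mi_size_threshold]
  removed_tab <- table(post$strain_id[!post$animal_id %in% keep])
  removed <- data.frame(strain_id = names(removed_tab),
                        n_removed = as.integer(removed_tab))
  inc <- post[post$animal_id %in% keep, ]
  mi_means <- tapply(inc$MI_size, inc$strain_id, mean)
  off <- names(mi_means)[abs(mi_means - comparability_target) > comparability_tol]
  if (length(off))
    warning("strains with mean MI size far from ", comparability_target,
            "% of LV (comparability screen): ", paste(off, collapse = ", "))
  list(
    records = records[records$animal_id %in% keep, ],
    survival = if (!is.null(survival)) survival[survival$animal_id %in% keep, ],
    removed = removed
  )
}

#' Per-strain survival of the myocardial rupture window
#'
#' Fraction of animals in each strain that did NOT die of LV free-wall
#' rupture within the given post-MI day window (default days 3-5, where
#' rupture mortality concentrates in the mouse ligation model). Deaths
#' outside the window or from other causes count as surviving the window.
#'
#' @param survival Survival log data.frame (`strain_id`, `animal_id`,
#'   `death_day`, `cause`).
#' @param window Integer day window `c(start, end)`, inclusive.
#' @return data.frame `strain_id`, `rupture_survival` (fraction in `[0, 1]`),
#'   `n_animals`.
#' @export
rupture_survival <- function(survival, window = c(3, 5)) {
  if (window[1] > window[2]) stop("window start must be <= end")
  n <- tapply(survival$animal_id, survival$strain_id, length)
  if (any(n == 0)) stop("strain with zero included animals")
  died <- !is.na(survival$death_day) & survival$cause == "rupture" &
    survival$death_day >= window[1] & survival$death_day <= window[2]
  d <- tapply(died, survival$strain_id, sum)
  data.frame(strain_id = names(n),
             rupture_survival = as.numeric(1 - d / n),
             n_animals = as.integer(n), row.names = NULL)
}

#' Flag strains with discordant delta-EF and LVD
#'
#' In strains developing systolic dysfunction the two remodeling hallmarks
#' move together (EF falls as the ventricle dilates); strains where the two
#' traits clearly disagree are excluded from LVSD/HF analyses. The default
#' rule flags a strain as discordant when the strain-level z-scores of
#' delta-EF and LVD have opposite signs and both exceed `z_gate` in absolute
#' value.
#'
#' @param trait_table data.frame with columns `strain_id`, `delta_EF`, `LVD`
#'   (>= 3 strains).
#' @param z_gate Minimum |z| for both traits before a sign disagreement
#'   counts as discordant.
#' @return The trait table with an added logical column `concordant`.
#' @export
concordance_flag <- function(trait_table, z_gate = 0.5) {
  if (nrow(trait_table) < 3) stop("need >= 3 strains")
  if (stats::sd(trait_table$delta_EF) == 0 || stats::sd(trait_table$LVD) == 0)
    stop("zero-variance trait")
  z1 <- as.numeric(scale(trait_table$delta_EF))
  z2 <- as.numeric(scale(trait_table$LVD))
  trait_table$concordant <- !(sign(z1) != sign(z2) &
                                abs(z1) > z_gate & abs(z2) > z_gate)
  trait_table
}

#' Build the per-strain trait table
#'
#' Applies the infarct-size inclusion filter, derives per-animal delta-EF and
#' LVD from the before/after echo rows, averages within strain (SD reported),
#' joins the rupture-window survival fraction, and flags discordant strains.
#'
#' @param records Per-animal echo records (before/after rows).
#' @param survival Optional survival log for the rupture trait.
#' @param mi_size_threshold Infarct-size inclusion threshold (percent of LV).
#' @param z_gate Concordance rule gate, see [concordance_flag()].
#' @return data.frame with `strain_id`, `delta_EF`, `LVD` (strain means),
#'   `delta_EF_sd`, `LVD_sd`, `rupture_survival` (if `survival` given),
#'   `n_animals`, `concordant`.
#' @export
derive_trait_table <- function(records, survival = NULL,
                               mi_size_threshold = 30, z_gate = 0.5) {
  flt <- apply_inclusion_filters(records, survival, mi_size_threshold)
  rec <- flt$records
  before <- rec[rec$timepoint == "before", ]
  after <- rec[rec$timepoint == "after", ]
  m <- match(after$animal_id, before$animal_id)
  if (anyNA(m)) stop("post-MI animals without baseline records: ",
                     paste(after$animal_id[is.na(m)], collapse = ", "))
  before <- before[m, ]
  dEF <- compute_delta_ef(before$EF, after$EF)
  lvd <- compute_lvd(before$LV_vol_d, after$LV_vol_d)
  agg <- function(x, f) as.numeric(tapply(x, after$strain_id, f))
  tab <- data.frame(
    strain_id = sort(unique(after$strain_id)),
    delta_EF = agg(dEF, mean), LVD = agg(lvd, mean),
    delta_EF_sd = agg(dEF, stats::sd), LVD_sd = agg(lvd, stats::sd),
    n_animals = as.integer(agg(dEF, length))
  )
  if (!is.null(survival)) {
    rs <- rupture_survival(flt$survival)
    tab$rupture_survival <- rs$rupture_survival[match(tab$strain_id, rs$strain_id)]
  }
  concordance_flag(tab, z_gate = z_gate)
}
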