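#' Collaborative Cross founder strain labels
#'
#' The canonical one-letter codes and strain names of the eight CC founders,
#' used to label founder haplotypes throughout the package.
#'
#' @format Character vector of length 8, names are the one-letter codes A-H.
#' @export
cc_founders <- c(
  A = "A/J", B = "C57BL/6J", C = "129S1/SvImJ", D = "NOD/ShiLtJ",
  E = "NZO/HlLtJ", F = "CAST/EiJ", G = "PWK/PhJ", H = "WSB/EiJ"
)

#' Simulate an eight-founder SNP panel
#'
#' Generates a synthetic genotype panel for the eight CC founder strains:
#' chromosome lengths, strictly increasing SNP positions, and a biallelic
#' (0 = reference, 1 = alternate) allele for each founder at each SNP.
#' Founder alleles are drawn independently Bernoulli(maf) per founder, with
#' the minor-allele frequency of each SNP drawn from `maf_distribution`.
#'
#' @param n_snps_per_chrom Number of SNPs per chromosome (>= 2).
#' @param n_chroms Number of chromosomes.
#' @param maf_distribution Function of one argument `n` returning `n`
#'   minor-allele frequencies in `[0, 1]`. Default: uniform on `[0.1, 0.5]`.
#' @param chrom_length Chromosome length in bp (recycled across chromosomes).
#' @param seed Integer seed; the panel is deterministic given the seed.
#'
#' @return An object of class `"founder_panel"`: a list with elements
#'   `founder_ids` (8 labels), `chromosomes` (data.frame: `name`, `length`),
#'   `map` (data.frame: `chrom`, `pos`, strictly increasing within
#'   chromosome), and `alleles` (SNPs x 8 integer matrix in `{0, 1}`).
#' @export
simulate_founders <- function(n_snps_per_chrom, n_chroms = 2,
                              maf_distribution = function(n) stats::runif(n, 0.1, 0.5),
                              chrom_length = 100e6, seed = 1) {
  if (n_snps_per_chrom < 2) stop("n_snps_per_chrom must be >= 2")
  if (n_chroms < 1) stop("n_chroms must be >= 1")
  set.seed(seed)
  chrom_length <- rep_len(chrom_length, n_chroms)
  chrom_names <- paste0("chr", seq_len(n_chroms))
  maps <- vector("list", n_chroms)
  for (c in seq_len(n_chroms)) {
    # sampling without replacement gives distinct, strictly increasing positions
    pos <- sort(sample.int(chrom_length[c] - 2L, n_snps_per_chrom)) + 1L
    maps[[c]] <- data.frame(chrom = chrom_names[c], pos = as.numeric(pos))
  }
  map <- do.call(rbind, maps)
  n_snps <- nrow(map)
  maf <- maf_distribution(n_snps)
  if (any(maf < 0 | maf > 1)) stop("maf_distribution must return values in [0, 1]")
  alleles <- matrix(
    as.integer(stats::runif(n_snps * 8L) < rep(maf, 8L)),
    nrow = n_snps, ncol = 8L
  )
  colnames(alleles) <- names(cc_founders)
  panel <- list(
    founder_ids = names(cc_founders),
    chromosomes = data.frame(name = chrom_names, length = chrom_length),
    map = map,
    alleles = alleles
  )
  class(panel) <- "founder_panel"
  panel
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("Founder SNP panel: 8 founders,", nrow(x$map), "SNPs on",
      nrow(x$chromosomes), "chromosome(s)\n")
  invisible(x)
}

#' Simulate one CC-like recombinant inbred strain genome
#'
#' Draws a founder mosaic directly: per chromosome the number of breakpoints
#' is Poisson with mean `expected_breakpoints_per_chrom`, breakpoint
#' positions are uniform, and each segment's founder identity is drawn
#' uniformly from the eight founders. The strain is fully inbred, so it
#' carries a single haplotype. Genotypes at panel SNPs are copied from the
#' donor founder, then flipped independently at `genotype_error_rate` and set
#' to missing at `missing_rate`.
#'
#' @param panel A `founder_panel`.
#' @param expected_breakpoints_per_chrom Poisson mean breakpoint count (>= 0).
#' @param genotype_error_rate Symmetric allele-flip probability in `[0, 0.5)`.
#' @param missing_rate Probability a call is set to `NA`.
#' @param strain_id Strain label.
#' @param seed Integer seed.
#'
#' @return An object of class `"mosaic_genome"`: list with `strain_id`,
#'   `segments` (data.frame `chrom`, `start`, `end`, `founder`; half-open
#'   `[start, end)` intervals tiling each chromosome), and `genotypes`
#'   (integer vector over panel SNPs, `NA` = missing).
#' @export
simulate_cc_strain <- function(panel, expected_breakpoints_per_chrom = 3,
                               genotype_error_rate = 0, missing_rate = 0,
                               strain_id = "CC001", seed = 1) {
  stopifnot(inherits(panel, "founder_panel"))
  if (nrow(panel$map) == 0) stop("empty panel")
  if (expected_breakpoints_per_chrom < 0) stop("expected breakpoints must be >= 0")
  if (genotype_error_rate < 0 || genotype_error_rate >= 0.5)
    stop("genotype_error_rate must be in [0, 0.5)")
  set.seed(seed)
  segs <- vector("list", nrow(panel$chromosomes))
  for (c in seq_len(nrow(panel$chromosomes))) {
    len <- panel$chromosomes$length[c]
    nbp <- stats::rpois(1, expected_breakpoints_per_chrom)
    bp <- sort(stats::runif(nbp, 1, len))
    starts <- c(0, bp)
    ends <- c(bp, len)
    founders <- sample.int(8L, nbp + 1L, replace = TRUE)
    segs[[c]] <- data.frame(
      chrom = panel$chromosomes$name[c],
      start = starts, end = ends, founder = founders
    )
  }
  segments <- do.call(rbind, segs)
  donor <- founder_at(segments, panel$map$chrom, panel$map$pos)
  geno <- panel$alleles[cbind(seq_len(nrow(panel$map)), donor)]
  if (genotype_error_rate > 0) {
    flip <- stats::runif(length(geno)) < genotype_error_rate
    geno[flip] <- 1L - geno[flip]
  }
  if (missing_rate > 0) {
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
  }
  g <- list(strain_id = strain_id, segments = segments, genotypes = geno)
  class(g) <- "mosaic_genome"
  g
}

# Donor founder index at given (chrom, pos) from a segment table.
founder_at <- function(segments, chrom, pos) {
  out <- integer(length(pos))
  for (cn in unique(chrom)) {
    seg <- segments[segments$chrom == cn, ]
    idx <- which(chrom == cn)
    j <- findInterval(pos[idx], seg$start)  # [start, end) tiling
    out[idx] <- seg$founder[j]
  }
  out
}

#' Simulate a cohort of CC-like strains
#'
#' Convenience wrapper around [simulate_cc_strain()] generating `n_strains`
#' independent mosaic genomes from one panel.
#'
#' @inheritParams simulate_cc_strain
#' @param n_strains Number of strains.
#' @return List of class `"cc_cohort"` with `genomes` (list of
#'   `mosaic_genome`) and `genotypes` (SNPs x strains integer matrix).
#' @export
simulate_cc_cohort <- function(panel, n_strains,
                               expected_breakpoints_per_chrom = 3,
                               genotype_error_rate = 0, missing_rate = 0,
                               seed = 1) {
  ids <- sprintf("CC%03d", seq_len(n_strains))
  genomes <- lapply(seq_len(n_strains), function(i) {
    simulate_cc_strain(panel, expected_breakpoints_per_chrom,
                       genotype_error_rate, missing_rate,
                       strain_id = ids[i], seed = seed + i)
  })
  geno <- vapply(genomes, `[[`, numeric(nrow(panel$map)), "genotypes")
  colnames(geno) <- ids
  structure(list(genomes = genomes, genotypes = geno, panel = panel),
            class = "cc_cohort")
}

#' Construct a planted-QTL specification
#'
#' @param chrom Chromosome name (must match the panel).
#' @param pos Position in bp.
#' @param effects Numeric length-8 additive founder effects in trait units;
#'   centered to mean zero on construction.
#' @param h2 Heritability of the strain-level trait, in `[0, 1)`: fraction of
#'   the variance of strain means explained by the QTL.
#' @param trait Which derived trait(s) the QTL drives.
#' @return Object of class `"qtl_spec"`.
#' @export
qtl_spec <- function(chrom, pos, effects, h2,
                     trait = c("both", "delta_EF", "LVD")) {
  stopifnot(length(effects) == 8, h2 >= 0, h2 < 1)
  trait <- match.arg(trait)
  structure(list(chrom = chrom, pos = pos,
                 effects = effects - mean(effects), h2 = h2, trait = trait),
            class = "qtl_spec")
}

#' Default baseline parameters for synthetic echo cohorts
#'
#' Strain-level means/SDs and animal-level SDs for the derived remodeling
#' traits, plus baseline echocardiography values used to back out per-animal
#' pre/post-MI measurements. Units: EF in percent, volumes in microlitres,
#' traits in percent. Animal-level trait SDs are exposed here (not
#' hard-coded) because no canonical within-strain variance exists; defaults
#' reflect typical murine post-MI echo variability.
#'
#' @return Named list of parameters.
#' @export
baseline_echo_params <- function() {
  list(
    EF_before_mean = 65, EF_before_sd = 3,
    LV_vol_before_mean = 55, LV_vol_before_sd = 5,
    dEF_mean = 50, dEF_strain_sd = 20, dEF_animal_sd = 8,
    LVD_mean = 40, LVD_strain_sd = 20, LVD_animal_sd = 8,
    MI_size_mean = 40, MI_size_sd = 4,
    SV_mean = 30, SV_sd = 4, LV_mass_mean = 110, LV_mass_sd = 12,
    BWt_mean = 28, BWt_sd = 2.5, HR_mean = 480, HR_sd = 35
  )
}

#' Simulate per-animal echocardiography records for a strain cohort
#'
#' Strain-level trait values are built as `baseline + genetic + deviation`:
#' the genetic value is the planted QTL's founder effect for the strain's
#' donor haplotype at the QTL locus, rescaled so that
#' `var(genetic) / var(strain means) = h2`; the strain deviation is Gaussian
#' with the complementary variance. Per-animal delta-EF and LVD add
#' animal-level Gaussian noise, and pre/post-MI EF and LV diastolic volumes
#' are then constructed so that the derived trait formulas return exactly the
#' per-animal values (with zero animal noise, strain means recover the
#' planted strain values exactly).
#'
#' @param cohort A `cc_cohort` (or list of `mosaic_genome`s plus a panel).
#' @param qtl A `qtl_spec`, or `NULL` for a purely polygenic-free null trait
#'   (strain means i.i.d. Gaussian).
#' @param n_animals_per_strain Animals per strain (>= 1).
#' @param params Baseline parameters, see [baseline_echo_params()].
#' @param seed Integer seed.
#'
#' @return data.frame of echo records, two rows per animal (timepoint
#'   `before` / `after`), columns `strain_id`, `animal_id`, `timepoint`,
#'   `EF`, `LV_vol_d`, `SV`, `LV_mass`, `BWt`, `heart_rate`, `MI_size`
#'   (post-MI rows only). Attribute `"truth"` holds the planted per-strain
#'   values and genetic components.
#' @export
simulate_cohort_traits <- function(cohort, qtl = NULL,
                                   n_animals_per_strain = 6,
                                   params = baseline_echo_params(),
                                   seed = 1) {
  if (n_animals_per_strain < 1) stop("n_animals_per_strain must be >= 1")
  genomes <- cohort$genomes
  panel <- cohort$panel
  n <- length(genomes)
  ids <- vapply(genomes, `[[`, character(1), "strain_id")
  set.seed(seed)

  genetic <- list(delta_EF = rep(0, n), LVD = rep(0, n))
  if (!is.null(qtl)) {
    stopifnot(inherits(qtl, "qtl_spec"))
    if (!qtl$chrom %in% panel$chromosomes$name ||
        qtl$pos < 0 ||
        qtl$pos > panel$chromosomes$length[match(qtl$chrom, panel$chromosomes$name)])
      stop("QTL position outside the panel")
    donor <- vapply(genomes, function(g) founder_at(g$segments, qtl$chrom, qtl$pos),
                    integer(1))
    g0 <- qtl$effects[donor]
    if (stats::var(g0) <= 0)
      warning("planted QTL is monomorphic in this cohort; genetic effect is zero")
    for (tr in c("delta_EF", "LVD")) {
      if (qtl$trait %in% c("both", tr) && stats::var(g0) > 0) {
        V <- if (tr == "delta_EF") params$dEF_strain_sd^2 else params$LVD_strain_sd^2
        genetic[[tr]] <- (g0 - mean(g0)) * sqrt(qtl$h2 * V / stats::var(g0))
      }
    }
  }

  strain_dEF <- params$dEF_mean + genetic$delta_EF +
    stats::rnorm(n, 0, sqrt(max(0, 1 - varfrac(genetic$delta_EF, params$dEF_strain_sd^2))) * params$dEF_strain_sd)
  strain_LVD <- params$LVD_mean + genetic$LVD +
    stats::rnorm(n, 0, sqrt(max(0, 1 - varfrac(genetic$LVD, params$LVD_strain_sd^2))) * params$LVD_strain_sd)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- n_animals_per_strain
    dEF <- strain_dEF[i] + stats::rnorm(m, 0, params$dEF_animal_sd)
    LVD <- strain_LVD[i] + stats::rnorm(m, 0, params$LVD_animal_sd)
    dEF <- pmax(dEF, -90); LVD <- pmax(LVD, -90)  # keep post-MI values physical
    ef_b <- pmin(stats::rnorm(m, params$EF_before_mean, params$EF_before_sd), 95)
    vol_b <- pmax(stats::rnorm(m, params$LV_vol_before_mean, params$LV_vol_before_sd), 10)
    ef_a <- ef_b / (1 + dEF / 100)
    vol_a <- vol_b * (1 + LVD / 100)
    an <- sprintf("%s_a%02d", ids[i], seq_len(m))
    common <- function(tp, ef, vol, mi) data.frame(
      strain_id = ids[i], animal_id = an, timepoint = tp, EF = ef,
      LV_vol_d = vol,
      SV = pmax(stats::rnorm(m, params$SV_mean, params$SV_sd), 5),
      LV_mass = pmax(stats::rnorm(m, params$LV_mass_mean, params$LV_mass_sd), 40),
      BWt = pmax(stats::rnorm(m, params$BWt_mean, params$BWt_sd), 15),
      heart_rate = pmax(stats::rnorm(m, params$HR_mean, params$HR_sd), 300),
      MI_size = mi
    )
    rows[[i]] <- rbind(
      common("before", ef_b, vol_b, NA_real_),
      common("after", ef_a, vol_a,
             pmin(pmax(stats::rnorm(m, params$MI_size_mean, params$MI_size_sd), 0), 100))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    strain_id = ids, strain_delta_EF = strain_dEF, strain_LVD = strain_LVD,
    genetic = genetic, qtl = qtl
  )
  out
}

varfrac <- function(g, V) if (V <= 0) 0 else stats::var(g) / V

#' Simulate a survival log with strain-specific rupture mortality
#'
#' Per-animal deaths from myocardial rupture occur on days 3-5 post MI with
#' strain-specific probability; all other animals are recorded alive.
#' Optionally the rupture probability is driven by a planted QTL through a
#' logistic link on the founder effects.
#'
#' @param cohort A `cc_cohort`.
#' @param base_prob Baseline per-animal rupture probability.
#' @param qtl Optional `qtl_spec`; its (centered) founder effects shift the
#'   log-odds of rupture.
#' @param n_animals_per_strain Animals per strain.
#' @param seed Integer seed.
#' @return data.frame `strain_id`, `animal_id`, `death_day` (`NA` if alive),
#'   `cause` in `{"rupture", "other", "alive"}`; attribute `"truth"` holds
#'   per-strain rupture probabilities.
#' @export
simulate_survival_log <- function(cohort, base_prob = 0.25, qtl = NULL,
                                  n_animals_per_strain = 6, seed = 1) {
  genomes <- cohort$genomes
  ids <- vapply(genomes, `[[`, character(1), "strain_id")
  set.seed(seed)
  eta <- stats::qlogis(base_prob) + numeric(length(ids))
  if (!is.null(qtl)) {
    donor <- vapply(genomes, function(g) founder_at(g$segments, qtl$chrom, qtl$pos),
                    integer(1))
    eta <- eta + qtl$effects[donor]
  }
  p <- stats::plogis(eta)
  rows <- lapply(seq_along(ids), function(i) {
    m <- n_animals_per_strain
    dead <- stats::runif(m) < p[i]
    data.frame(
      strain_id = ids[i],
      animal_id = sprintf("%s_a%02d", ids[i], seq_len(m)),
      death_day = ifelse(dead, sample(3:5, m, replace = TRUE), NA_integer_),
      cause = ifelse(dead, "rupture", "alive")
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(strain_id = ids, rupture_prob = p)
  out
}

#' Fiber-field ground truth for synthetic scar images
#'
#' @param mu True mean axial angle in degrees, wrapped to `[0, 180)`.
#' @param kappa von Mises concentration (>= 0), applied on doubled angles.
#' @param fiber_density Fibers per 1000 pixels squared.
#' @param pixel_size Pixel edge length in micrometres.
#' @return Object of class `"fiber_truth"`.
#' @export
fiber_truth <- function(mu, kappa, fiber_density = 2, pixel_size = 2.21) {
  if (kappa < 0) stop("kappa must be >= 0")
  structure(list(mu = mu %% 180, kappa = kappa,
                 fiber_density = fiber_density, pixel_size = pixel_size),
            class = "fiber_truth")
}

# von Mises sampler (Best & Fisher rejection method), angles in radians on
# (-pi, pi]. kappa = 0 falls back to uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  (out + mu + pi) %% (2 * pi) - pi
}

#' Simulate a paired polarized/brightfield scar image
#'
#' Renders anti-aliased fiber segments whose axial orientations are drawn
#' from a doubled-angle von Mises distribution (angles doubled, drawn with
#' concentration `kappa` about `2 * mu`, then halved). The polarized channel
#' shows fibers bright on a dark background; the blue-filter brightfield
#' channel shows the same fibers dark on a bright background. Additive
#' Gaussian noise is applied to both channels.
#'
#' @param truth A [fiber_truth()].
#' @param image_shape Integer vector `c(rows, cols)`, each >= 64.
#' @param noise_sd Gaussian noise SD on the `[0, 1]` intensity scale.
#' @param fiber_length Segment length in pixels.
#' @param seed Integer seed.
#' @return Object of class `"scar_image_pair"`: list with matrices
#'   `polarized` and `brightfield_blue` in `[0, 1]`, `pixel_size`, and
#'   ground-truth `angles` (degrees, axial) plus the `truth` object.
#' @export
simulate_scar_image_pair <- function(truth, image_shape = c(256, 256),
                                     noise_sd = 0.02, fiber_length = 21,
                                     seed = 1) {
  stopifnot(inherits(truth, "fiber_truth"))
  if (any(image_shape < 64)) stop("image_shape must be at least 64 x 64")
  set.seed(seed)
  nr <- image_shape[1]; nc <- image_shape[2]
  n_fibers <- round(truth$fiber_density * nr * nc / 1000)
  img <- matrix(0, nr, nc)
  angles <- numeric(0)
  if (n_fibers > 0) {
    phi2 <- rvonmises(n_fibers, 2 * truth$mu * pi / 180, truth$kappa)
    theta <- ((phi2 / 2) * 180 / pi) %% 180
    angles <- theta
    cx <- stats::runif(n_fibers, 1, nc)
    cy <- stats::runif(n_fibers, 1, nr)
    th <- theta * pi / 180
    tseq <- seq(-fiber_length / 2, fiber_length / 2, by = 0.25)
    # sample points along every segment, then deposit by bilinear splat,
    # accumulating all contributions per pixel
    xs <- as.vector(tseq %o% cos(th) + rep(cx, each = length(tseq)))
    ys <- as.vector(tseq %o% sin(th) + rep(cy, each = length(tseq)))
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    acc <- numeric(nr * nc)
    for (k in 0:3) {
      dx <- k %% 2; dy <- k %/% 2
      xi <- x0 + dx; yi <- y0 + dy
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * 0.25
      ok <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr
      if (any(ok)) {
        li <- (xi[ok] - 1) * nr + yi[ok]
        sums <- rowsum(w[ok], li)
        acc[as.integer(rownames(sums))] <-
          acc[as.integer(rownames(sums))] + sums[, 1]
      }
    }
    img <- matrix(pmin(acc, 1), nr, nc)
  }
  pol <- pmin(pmax(img + stats::rnorm(nr * nc, 0, noise_sd), 0), 1)
  bf <- pmin(pmax(1 - img + stats::rnorm(nr * nc, 0, noise_sd), 0), 1)
  structure(list(polarized = pol, brightfield_blue = bf,
                 pixel_size = truth$pixel_size, angles = angles,
                 truth = truth),
            class = "scar_image_pair")
}

#' Simulate a transcripts-by-strains expression matrix with planted correlates
#'
#' `n_correlated` transcripts are constructed as affine functions of the
#' standardized trait plus Gaussian noise, calibrated so the expected sample
#' correlation with the trait is approximately `target_r`; the remaining
#' transcripts are independent of the trait. Values are on a positive
#' log2-intensity-like scale.
#'
#' @param n_transcripts Total number of transcripts.
#' @param strain_traits Named numeric vector of strain trait values (names =
#'   strain ids); must not be constant when `n_correlated > 0`.
#' @param n_correlated Number of trait-correlated transcripts (first rows).
#' @param target_r Target correlation, `|target_r| <= 1`.
#' @param noise_sd SD of the independent transcripts on the log2 scale.
#' @param seed Integer seed.
#' @return Numeric matrix `n_transcripts x n_strains` with transcript row
#'   names `Tx00001, ...`; attribute `"truth"` lists the planted correlated
#'   transcript ids and `target_r`.
#' @export
simulate_expression <- function(n_transcripts, strain_traits, n_correlated,
                                target_r = 0.9, noise_sd = 0.5, seed = 1) {
  if (n_correlated < 0 || n_correlated > n_transcripts)
    stop("n_correlated must be in [0, n_transcripts]")
  if (abs(target_r) > 1) stop("|target_r| must be <= 1")
  n_strains <- length(strain_traits)
  if (n_correlated > 0 && stats::sd(strain_traits) == 0)
    stop("strain_traits is constant; cannot plant correlated transcripts")
  set.seed(seed)
  z <- if (stats::sd(strain_traits) > 0)
    as.numeric(scale(strain_traits)) else numeric(n_strains)
  mat <- matrix(NA_real_, n_transcripts, n_strains)
  base <- stats::runif(n_transcripts, 6, 12)
  amp <- 0.5  # log2 units per trait SD
  for (i in seq_len(n_transcripts)) {
    if (i <= n_correlated) {
      x <- target_r * z + sqrt(max(0, 1 - target_r^2)) * stats::rnorm(n_strains)
      mat[i, ] <- base[i] + amp * x
    } else {
      mat[i, ] <- base[i] + noise_sd * stats::rnorm(n_strains)
    }
  }
  mat <- pmax(mat, 1e-6)
  rownames(mat) <- sprintf("Tx%05d", seq_len(n_transcripts))
  colnames(mat) <- names(strain_traits)
  attr(mat, "truth") <- list(
    correlated = rownames(mat)[seq_len(n_correlated)], target_r = target_r
  )
  mat
}
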