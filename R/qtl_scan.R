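#' Kinship matrix from founder dosages
#'
#' `K[a, b]` is the mean over loci of the inner product of the founder-dosage
#' vectors of strains `a` and `b`, rescaled so the mean diagonal equals 1.
#' Used as the random-effect covariance in the mixed-model scan to correct
#' for cryptic relatedness between strains. A leave-one-chromosome-out
#' variant is available via `exclude_chromosome`.
#'
#' @param dosages List from [founder_dosages()] (`dosages` array loci x
#'   strains x 8, `map`).
#' @param exclude_chromosome Optional chromosome name to leave out.
#' @return Symmetric positive semi-definite strains x strains matrix with
#'   attribute `"method"`.
#' @export
kinship_matrix <- function(dosages, exclude_chromosome = NULL) {
  D <- dosages$dosages
  map <- dosages$map
  if (!is.null(exclude_chromosome)) {
    keep <- map$chrom != exclude_chromosome
    if (!any(keep)) stop("excluding that chromosome leaves no loci")
    D <- D[keep, , , drop = FALSE]
  }
  n_loci <- dim(D)[1]; n_strains <- dim(D)[2]
  if (n_strains < 2) stop("need >= 2 strains")
  if (n_loci < 1) stop("empty posterior set")
  # flatten to (loci*founders) x strains; K = X'X / n_loci
  X <- matrix(aperm(D, c(1, 3, 2)), ncol = n_strains)
  K <- crossprod(X) / n_loci
  K <- K / mean(diag(K))
  dimnames(K) <- list(dimnames(D)[[2]], dimnames(D)[[2]])
  attr(K, "method") <- paste0("dosage-inner-product",
                              if (!is.null(exclude_chromosome))
                                paste0(" (LOCO ", exclude_chromosome, ")"))
  K
}

# Profile ML log-likelihood machinery on the eigenbasis of K.
# Model: y = X b + g + e, g ~ N(0, sg2 K), e ~ N(0, se2 I).
# With K = U diag(ev) U', rotate yr = U'y, Xr = U'X; for lambda = sg2/se2 the
# covariance is se2 * diag(lambda*ev + 1), so each locus fit is weighted LS.

# Weighted residual sum of squares of yr on Xr with weights w (qr-based,
# tolerant of rank deficiency).
wrss <- function(Xr, yr, sw) {
  fit <- stats::lm.fit(Xr * sw, yr * sw)
  sum(fit$residuals^2)
}

profile_ml <- function(lambda, ev, Xr, yr) {
  v <- lambda * ev + 1
  sw <- 1 / sqrt(v)
  n <- length(yr)
  rss <- wrss(Xr, yr, sw)
  se2 <- rss / n
  -n / 2 * (log(2 * pi * se2) + 1) - sum(log(v)) / 2
}

# Fit the null mixed model by ML: returns lambda, se2, loglik.
fit_null_mm <- function(ev, Xr, yr) {
  opt <- stats::optimize(function(ll) -profile_ml(exp(ll), ev, Xr, yr),
                         interval = c(log(1e-6), log(1e6)), tol = 1e-6)
  # compare against the boundary lambda -> 0 (no genetic variance)
  ll0 <- profile_ml(0, ev, Xr, yr)
  llopt <- -opt$objective
  if (ll0 >= llopt) {
    lambda <- 0; ll <- ll0
  } else {
    lambda <- exp(opt$minimum); ll <- llopt
  }
  v <- lambda * ev + 1
  rss <- wrss(Xr, yr, 1 / sqrt(v))
  list(lambda = lambda, se2 = rss / length(yr), loglik = ll)
}

# Precompute everything that does not depend on the trait: eigenbasis of K,
# rotated intercept and per-locus rotated design matrices. Reused across
# permutations, where only y changes.
scan_engine <- function(dosages, K, exclude_founders = NULL) {
  D <- dosages$dosages
  n <- dim(D)[2]
  founder_ids <- dimnames(D)[[3]]
  use_f <- seq_len(8)
  if (!is.null(exclude_founders)) {
    drop_f <- if (is.character(exclude_founders))
      match(exclude_founders, founder_ids) else exclude_founders
    use_f <- setdiff(use_f, drop_f)
  }
  eig <- eigen(K, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  U <- eig$vectors
  onesr <- drop(crossprod(U, rep(1, n)))
  n_loci <- dim(D)[1]
  Xr_list <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    Xl <- D[l, , use_f, drop = TRUE]
    # columns sum to 1 -> drop one founder column (collinear with intercept)
    Xr_list[[l]] <- crossprod(U, cbind(1, Xl[, -length(use_f), drop = FALSE]))
  }
  list(U = U, ev = ev, onesr = onesr, Xr_list = Xr_list, use_f = use_f,
       founder_ids = founder_ids, map = dosages$map, n = n)
}

# LOD curve for one trait vector using a precomputed engine.
engine_lod <- function(eng, y, keep_coefs = FALSE) {
  n <- eng$n
  yr <- drop(crossprod(eng$U, y))
  X0 <- matrix(eng$onesr, ncol = 1)
  null <- fit_null_mm(eng$ev, X0, yr)
  sw <- 1 / sqrt(null$lambda * eng$ev + 1)
  rss0 <- wrss(X0, yr, sw)
  yw <- yr * sw
  n_loci <- length(eng$Xr_list)
  lod <- numeric(n_loci)
  coefs <- if (keep_coefs)
    matrix(0, n_loci, 8, dimnames = list(NULL, eng$founder_ids))
  for (l in seq_len(n_loci)) {
    Xw <- eng$Xr_list[[l]] * sw
    if (keep_coefs) {
      fit <- stats::lm.fit(Xw, yw)
      b <- fit$coefficients[-1]
      b[is.na(b)] <- 0                     # collinear dosage -> reference
      eff <- numeric(8)
      eff[eng$use_f] <- c(b, 0)
      coefs[l, eng$use_f] <- eff[eng$use_f] - mean(eff[eng$use_f])
    } else {
      fit <- stats::.lm.fit(Xw, yw)
    }
    lod[l] <- n / 2 * log10(rss0 / sum(fit$residuals^2))
  }
  list(lod = pmax(lod, 0), coefs = coefs, mm = null)
}

#' Mixed-model genome scan on founder dosages
#'
#' At each locus, the strain trait is regressed on the eight founder dosages
#' under the covariance of a null mixed model `y = mu + g + e` with
#' `g ~ N(0, sg2 * K)`; variance components are estimated once under the null
#' by maximum likelihood (EMMA-style) and reused at every locus. The LOD
#' score is the log10 likelihood ratio of the locus model against the
#' intercept-only null. Because dosage columns sum to one at every locus, one
#' founder column is dropped during fitting and the coefficients are
#' re-expressed as eight founder effects centered to mean zero.
#'
#' @param trait Named numeric vector of strain trait values.
#' @param dosages List from [founder_dosages()].
#' @param K Kinship matrix from [kinship_matrix()].
#' @param exclude_founders Optional character/integer vector of founders whose
#'   dosage columns are dropped from the locus design (e.g. a founder absent
#'   from the mapping population).
#' @param engine Optional precomputed internal scan engine (reused across
#'   permutations/replicates sharing the same genotypes and kinship).
#' @return data.frame of class `"qtl_scan"`: `chrom`, `pos`, `LOD`, eight
#'   centered founder-effect columns; attributes `"mm"` (null variance
#'   components) and `"n"` (strains).
#' @export
scan_qtl <- function(trait, dosages, K, exclude_founders = NULL,
                     engine = NULL) {
  n <- dim(dosages$dosages)[2]
  if (length(trait) != n) stop("trait length does not match strain count")
  if (n < 10) stop("need >= 10 strains")
  if (stats::sd(trait) == 0) stop("constant trait")
  if (is.null(engine)) engine <- scan_engine(dosages, K, exclude_founders)
  res <- engine_lod(engine, trait, keep_coefs = TRUE)
  out <- data.frame(chrom = engine$map$chrom, pos = engine$map$pos,
                    LOD = res$lod)
  out <- cbind(out, res$coefs)
  class(out) <- c("qtl_scan", "data.frame")
  attr(out, "mm") <- res$mm
  attr(out, "n") <- n
  out
}

#' Genome-wide permutation significance thresholds
#'
#' Permutes the trait values across strains, re-runs the full genome scan
#' (null variance components re-estimated per permutation), and takes
#' empirical quantiles of the genome-wide maximum LOD: the threshold at level
#' `alpha` is the `ceiling((1 - alpha) * n_perm)`-th order statistic.
#'
#' @param trait,dosages,K,exclude_founders,engine As in [scan_qtl()].
#' @param n_perm Number of permutations (>= 100).
#' @param alphas Genome-wide significance levels; defaults are the
#'   significant / approaching-significance / suggestive levels.
#' @param seed Integer seed for the permutations.
#' @return List of class `"qtl_thresholds"`: `thresholds` (named by alpha),
#'   `max_lods` (the permutation null distribution), `n_perm`, `seed`.
#' @export
permutation_thresholds <- function(trait, dosages, K, n_perm = 1000,
                                   alphas = c(0.05, 0.10, 0.63),
                                   exclude_founders = NULL, seed = 1,
                                   engine = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (any(alphas < 1 / n_perm))
    stop("alpha below 1/n_perm cannot be estimated")
  set.seed(seed)
  n <- length(trait)
  eng <- if (is.null(engine)) scan_engine(dosages, K, exclude_founders)
         else engine
  max_lods <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    yp <- trait[sample.int(n)]
    max_lods[p] <- max(engine_lod(eng, yp)$lod)
  }
  srt <- sort(max_lods)
  thr <- srt[pmin(ceiling((1 - alphas) * n_perm), n_perm)]
  names(thr) <- paste0("alpha_", alphas)
  structure(list(thresholds = thr, max_lods = max_lods,
                 n_perm = n_perm, seed = seed),
            class = "qtl_thresholds")
}

#' Two-LOD-drop support interval with 10 kb padding
#'
#' Walks outward from the peak locus to the first loci (on each side, same
#' chromosome) whose LOD falls at least `drop` units below the peak; the
#' interval boundaries are those loci's positions extended by `pad` bp to
#' compensate for non-uniform SNP spacing, clipped to the chromosome ends.
#' If the LOD never drops on a side, the interval extends to the chromosome
#' end with a warning.
#'
#' @param scan A `qtl_scan`.
#' @param peak Row index of the peak locus (default: genome-wide maximum).
#' @param drop LOD drop defining the support interval (default 2).
#' @param pad Padding in bp added to each boundary (default 10 kb).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   clipping (otherwise clipped to the first/last locus +/- pad).
#' @return List of class `"support_interval"`: `chrom`, `peak_pos`,
#'   `peak_lod`, `start`, `end`.
#' @export
support_interval <- function(scan, peak = which.max(scan$LOD), drop = 2.0,
                             pad = 10000, chrom_lengths = NULL) {
  cn <- scan$chrom[peak]
  idx <- which(scan$chrom == cn)
  pos <- scan$pos[idx]; lod <- scan$LOD[idx]
  p <- match(peak, idx)
  if ((p > 1 && lod[p - 1] > lod[p]) ||
      (p < length(idx) && lod[p + 1] > lod[p]))
    stop("peak is not a local maximum")
  cut <- lod[p] - drop
  left <- p; while (left > 1 && lod[left] > cut) left <- left - 1
  right <- p; while (right < length(idx) && lod[right] > cut) right <- right + 1
  if (lod[left] > cut || lod[right] > cut)
    warning("LOD never drops ", drop, " below the peak on one side; ",
            "interval extends to the chromosome end")
  lo <- pos[left] - pad
  hi <- pos[right] + pad
  cl <- if (!is.null(chrom_lengths)) c(0, chrom_lengths[[cn]]) else c(0, Inf)
  structure(list(chrom = cn, peak_pos = scan$pos[peak],
                 peak_lod = scan$LOD[peak],
                 start = max(lo, cl[1]), end = min(hi, cl[2])),
            class = "support_interval")
}

#' Founder effects and Wald tests at a peak locus
#'
#' Refits the generalized least squares locus model at the peak under the
#' null-model covariance and reports the eight centered founder coefficients
#' with standard errors and two-sided Wald t-tests against zero
#' (df = n - 8). Collinear dosage columns are reported with a zero
#' coefficient and `NA` p-value.
#'
#' @param trait,dosages,K As in [scan_qtl()].
#' @param peak Locus row index.
#' @return data.frame: `founder`, `effect`, `se`, `t`, `p_value`.
#' @export
founder_effects <- function(trait, dosages, K, peak) {
  D <- dosages$dosages
  n <- dim(D)[2]
  founder_ids <- dimnames(D)[[3]]
  eig <- eigen(K, symmetric = TRUE)
  ev <- pmax(eig$values, 0); U <- eig$vectors
  yr <- drop(crossprod(U, trait))
  onesr <- drop(crossprod(U, rep(1, n)))
  null <- fit_null_mm(ev, matrix(onesr, ncol = 1), yr)
  sw <- 1 / sqrt(null$lambda * ev + 1)
  Xl <- D[peak, , , drop = TRUE]
  Xr <- crossprod(U, cbind(1, Xl[, -8, drop = FALSE])) * sw
  yw <- yr * sw
  fit <- stats::lm.fit(Xr, yw)
  b <- fit$coefficients
  ok <- !is.na(b)
  dfres <- n - sum(ok)
  sigma2 <- sum(fit$residuals^2) / dfres
  XtXi <- chol2inv(chol(crossprod(Xr[, ok, drop = FALSE])))
  # centered effects: eff_k = b_k - mean(b_1..b_8) with b_8 = 0 (dropped col)
  b_full <- numeric(8); b_full[1:7] <- ifelse(ok[-1], b[-1], 0)
  eff <- b_full - mean(b_full)
  # contrast matrix over the estimated coefficients (intercept + 7 dosages)
  Cmat <- matrix(0, 8, length(b))
  for (k in 1:8) {
    ck <- numeric(7)
    if (k <= 7) ck[k] <- 1
    ck <- ck - 1 / 8 * rep(1, 7) * 1  # subtract mean of the 8 effects
    Cmat[k, -1] <- ck
  }
  Cok <- Cmat[, ok, drop = FALSE]
  se <- sqrt(pmax(rowSums((Cok %*% XtXi) * Cok), 0) * sigma2)
  tstat <- eff / se
  pv <- 2 * stats::pt(-abs(tstat), dfres)
  collinear <- c(FALSE, !ok[-1])  # dosage columns dropped by the QR
  if (any(collinear[1:7]))
    warning("collinear dosage columns at the peak; coefficients set to reference")
  data.frame(founder = founder_ids, effect = eff, se = se, t = tstat,
             p_value = pv)
}

#' Prioritize candidate SNPs within a QTL support interval
#'
#' Filters an annotated variant table to the support interval, retains
#' variants whose alternate allele is carried by all implicated founders, and
#' ranks by (1) the alternate allele being private to the implicated
#' founders, (2) consequence severity (missense/splice over others), and
#' (3) predicted deleteriousness (SIFT < 0.05).
#'
#' @param interval A `support_interval`.
#' @param variants data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `consequence`, eight founder allele columns (0/1) named as the panel
#'   founders, and `sift` (NA allowed).
#' @param implicated_founders Non-empty character vector of founder ids.
#' @return The retained variants with added `tier` (1 = best) and `rank`,
#'   sorted by rank.
#' @export
prioritize_snps <- function(interval, variants, implicated_founders) {
  if (!length(implicated_founders)) stop("implicated founder set is empty")
  v <- variants[variants$chrom == interval$chrom &
                  variants$pos >= interval$start &
                  variants$pos <= interval$end, , drop = FALSE]
  if (!nrow(v)) stop("no variants in the support interval")
  fcols <- intersect(names(cc_founders), names(v))
  stopifnot(length(fcols) == 8)
  alle <- as.matrix(v[, fcols])
  imp <- match(implicated_founders, fcols)
  carried_all <- rowSums(alle[, imp, drop = FALSE] == 1) == length(imp)
  v <- v[carried_all, , drop = FALSE]
  if (!nrow(v)) return(cbind(v, tier = integer(0), rank = integer(0)))
  alle <- as.matrix(v[, fcols])
  private <- rowSums(alle[, -imp, drop = FALSE] == 1) == 0
  severe <- grepl("missense|splice", v$consequence, ignore.case = TRUE)
  deleterious <- !is.na(v$sift) & v$sift < 0.05
  tier <- 1L + (!private) * 4L + (!severe) * 2L + (!deleterious) * 1L
  ord <- order(tier, v$pos)
  v <- v[ord, , drop = FALSE]
  v$tier <- tier[ord]
  v$rank <- seq_len(nrow(v))
  v
}
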