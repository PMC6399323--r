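# Shared mapping fixture: 50 strains, 2 chromosomes, haplotypes inferred
# through the HMM so the scan runs on posterior dosages as in the pipeline.
mapping_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- tiny_cohort(n_snps = 80, n_chroms = 2, n_strains = 50, bp = 3,
                        err = 0.002, seed = 91)
      probs <- lapply(seq_len(50), function(i)
        infer_haplotypes(fx$cohort$genotypes[, i], fx$panel))
      names(probs) <- colnames(fx$cohort$genotypes)
      dos <- founder_dosages(probs)
      cache <<- list(panel = fx$panel, cohort = fx$cohort, dosages = dos,
                     K = kinship_matrix(dos))
    }
    cache
  }
})

test_that("kinship is symmetric PSD with unit mean diagonal and LOCO support", {
  fx <- mapping_fixture()
  K <- fx$K
  expect_equal(K, t(K))
  expect_equal(mean(diag(K)), 1)
  expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-8)
  # self-similarity dominates
  expect_true(all(diag(K) >= apply(K - diag(diag(K)), 1, max)))
  K1 <- kinship_matrix(fx$dosages, exclude_chromosome = "chr1")
  expect_equal(mean(diag(K1)), 1)
  expect_false(isTRUE(all.equal(K, K1)))
})

test_that("disjoint founder mosaics have near-zero kinship", {
  panel <- simulate_founders(200, 1, seed = 92)
  seg <- function(f) data.frame(chrom = "chr1", start = 0,
                                end = panel$chromosomes$length, founder = f)
  probs <- lapply(1:3, function(f) {
    geno <- panel$alleles[, f]
    infer_haplotypes(geno, panel, hmm_params(emission_error = 0.001))
  })
  names(probs) <- paste0("s", 1:3)
  K <- kinship_matrix(founder_dosages(probs))
  expect_gt(min(diag(K)), 0.9)
  expect_lt(max(K[upper.tri(K)]), 0.05)
})

test_that("mixed-model LOD matches the ordinary-regression LRT when K = I", {
  fx <- mapping_fixture()
  n <- 20
  dos <- list(dosages = fx$dosages$dosages[1:25, 1:n, , drop = FALSE],
              map = fx$dosages$map[1:25, ])
  K <- diag(n)
  dimnames(K) <- list(colnames(fx$cohort$genotypes)[1:n],
                      colnames(fx$cohort$genotypes)[1:n])
  set.seed(93)
  y <- rnorm(n)
  sc <- scan_qtl(y, dos, K)
  for (l in c(1, 7, 25)) {
    X <- dos$dosages[l, , 1:7]
    alt <- stats::lm(y ~ X)
    null <- stats::lm(y ~ 1)
    lod_oracle <- (as.numeric(stats::logLik(alt)) -
                     as.numeric(stats::logLik(null))) / log(10)
    expect_equal(sc$LOD[l], lod_oracle, tolerance = 1e-6)
  }
})

test_that("LOD is non-negative and invariant to affine trait transforms", {
  fx <- mapping_fixture()
  set.seed(94)
  y <- rnorm(50)
  s1 <- scan_qtl(y, fx$dosages, fx$K)
  expect_true(all(s1$LOD >= 0))
  s2 <- scan_qtl(2 * y + 3, fx$dosages, fx$K)
  expect_equal(s1$LOD, s2$LOD, tolerance = 1e-8)
  expect_error(scan_qtl(rep(1, 50), fx$dosages, fx$K), "constant")
})

test_that("founder-effect coefficients are centered and respect exclusions", {
  fx <- mapping_fixture()
  set.seed(95)
  y <- rnorm(50)
  sc <- scan_qtl(y, fx$dosages, fx$K)
  co <- as.matrix(sc[, names(cc_founders)])
  expect_true(all(abs(rowMeans(co)) < 1e-10))
  sc2 <- scan_qtl(y, fx$dosages, fx$K, exclude_founders = "C")
  expect_true(all(sc2$C == 0))
})

test_that("permutation thresholds are ordered, deterministic, and stable in n_perm", {
  fx <- mapping_fixture()
  set.seed(96)
  y <- rnorm(50)
  thr <- permutation_thresholds(y, fx$dosages, fx$K, n_perm = 100, seed = 1)
  expect_true(thr$thresholds["alpha_0.05"] >= thr$thresholds["alpha_0.1"])
  expect_true(thr$thresholds["alpha_0.1"] >= thr$thresholds["alpha_0.63"])
  thr2 <- permutation_thresholds(y, fx$dosages, fx$K, n_perm = 100, seed = 1)
  expect_identical(thr$thresholds, thr2$thresholds)
  # suggestive-level threshold agrees between 100 and 400 permutations within
  # binomial quantile MC error (central quantiles are stable)
  thr4 <- permutation_thresholds(y, fx$dosages, fx$K, n_perm = 400, seed = 2)
  q63_se <- diff(quantile(thr4$max_lods, c(0.25, 0.5)))  # coarse spread scale
  expect_lt(abs(thr$thresholds["alpha_0.63"] - thr4$thresholds["alpha_0.63"]),
            max(0.5, 2 * q63_se))
  expect_error(permutation_thresholds(y, fx$dosages, fx$K, n_perm = 50),
               ">= 100")
})

test_that("support intervals follow the two-LOD-drop plus padding rule", {
  # triangular LOD curve peaking at 10, slope 1 per locus, loci 1 kb apart
  lod <- 10 - abs(-10:10)
  sc <- data.frame(chrom = "chr1", pos = seq_along(lod) * 1000, LOD = lod)
  class(sc) <- c("qtl_scan", "data.frame")
  iv <- support_interval(sc, peak = 11, drop = 2, pad = 1500)
  expect_equal(iv$peak_pos, 11000)
  # first loci with LOD <= 8 are 2 out on each side, then the padding
  expect_equal(c(iv$start, iv$end), c(9000 - 1500, 13000 + 1500))
  # padding clips at the chromosome start
  ivc <- support_interval(sc, peak = 11, drop = 2, pad = 10000)
  expect_equal(c(ivc$start, ivc$end), c(0, 23000))
  iv0 <- support_interval(sc, peak = 11, drop = 2, pad = 0)
  expect_equal(c(iv0$start, iv0$end), c(9000, 13000))
  flat <- data.frame(chrom = "chr1", pos = (1:20) * 1000, LOD = rep(5, 20))
  class(flat) <- c("qtl_scan", "data.frame")
  expect_warning(ivf <- support_interval(flat, peak = 10, pad = 0),
                 "chromosome end")
  expect_equal(c(ivf$start, ivf$end), c(1000, 20000))
})

test_that("planted QTL is mapped with the correct conferring founder", {
  fx <- mapping_fixture()
  pos1 <- fx$panel$map$pos[fx$panel$map$chrom == "chr1"]
  qtl_pos <- pos1[40]
  q <- qtl_spec("chr1", qtl_pos, effects = c(0, 0, 0, 0, 0, 0, 2, 0),
                h2 = 0.6, trait = "LVD")
  rec <- simulate_cohort_traits(fx$cohort, qtl = q,
                                n_animals_per_strain = 6, seed = 97)
  tab <- derive_trait_table(rec)
  y <- tab$LVD
  names(y) <- tab$strain_id
  sc <- scan_qtl(y[colnames(fx$cohort$genotypes)], fx$dosages, fx$K)
  peak <- which.max(sc$LOD)
  expect_equal(sc$chrom[peak], "chr1")
  iv <- support_interval(sc, peak)
  expect_true(iv$start <= qtl_pos && qtl_pos <= iv$end)
  fe <- founder_effects(y[colnames(fx$cohort$genotypes)], fx$dosages, fx$K,
                        peak)
  expect_equal(fe$founder[which.min(fe$p_value)], "G")
  expect_equal(fe$founder[which.max(abs(fe$effect))], "G")
  expect_equal(sum(fe$effect), 0, tolerance = 1e-9)
})

test_that("null founder-effect p-values are uniform under repeated simulation", {
  fx <- mapping_fixture()
  set.seed(98)
  pvals <- unlist(lapply(1:40, function(i) {
    y <- rnorm(50)
    founder_effects(y, fx$dosages, fx$K, peak = sample.int(150, 1))$p_value
  }))
  pvals <- pvals[is.finite(pvals)]
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("mapping power increases with planted heritability", {
  fx <- mapping_fixture()
  pos1 <- fx$panel$map$pos[fx$panel$map$chrom == "chr1"]
  peak_lods <- vapply(c(0.1, 0.3, 0.5), function(h2) {
    lods <- vapply(1:5, function(rep) {
      q <- qtl_spec("chr1", pos1[40], effects = c(3, 0, 0, 0, 0, 0, 0, 0),
                    h2 = h2, trait = "LVD")
      rec <- simulate_cohort_traits(fx$cohort, qtl = q,
                                    n_animals_per_strain = 6,
                                    seed = 1000 * h2 * 100 + rep)
      tab <- derive_trait_table(rec)
      y <- tab$LVD; names(y) <- tab$strain_id
      max(scan_qtl(y[colnames(fx$cohort$genotypes)], fx$dosages, fx$K)$LOD)
    }, numeric(1))
    mean(lods)
  }, numeric(1))
  expect_true(all(diff(peak_lods) > 0))
})

test_that("candidate SNPs are filtered to the interval and ranked by tier", {
  iv <- structure(list(chrom = "chr1", peak_pos = 5e6, peak_lod = 8,
                       start = 4e6, end = 6e6),
                  class = "support_interval")
  mk <- function(id, pos, cons, alleles, sift) {
    v <- data.frame(snp_id = id, chrom = "chr1", pos = pos,
                    consequence = cons, sift = sift)
    v[names(cc_founders)] <- as.list(alleles)
    v
  }
  variants <- rbind(
    mk("private_missense", 4.5e6, "missense_variant",
       c(0, 0, 0, 0, 0, 0, 1, 0), 0.01),
    mk("shared_missense", 5.2e6, "missense_variant",
       c(1, 0, 1, 0, 0, 1, 1, 0), 0.01),
    mk("private_synonymous", 5.5e6, "synonymous_variant",
       c(0, 0, 0, 0, 0, 0, 1, 0), NA),
    mk("outside", 8e6, "missense_variant",
       c(0, 0, 0, 0, 0, 0, 1, 0), 0.01),
    mk("not_carried", 4.8e6, "missense_variant",
       c(1, 1, 0, 0, 0, 0, 0, 0), 0.01)
  )
  ranked <- prioritize_snps(iv, variants, implicated_founders = "G")
  expect_equal(ranked$snp_id[1], "private_missense")
  expect_false("outside" %in% ranked$snp_id)
  expect_false("not_carried" %in% ranked$snp_id)
  expect_lt(ranked$tier[ranked$snp_id == "private_missense"],
            ranked$tier[ranked$snp_id == "shared_missense"])
  expect_lt(ranked$tier[ranked$snp_id == "private_synonymous"],
            ranked$tier[ranked$snp_id == "shared_missense"])
  expect_error(prioritize_snps(iv, variants, character(0)), "empty")
})
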