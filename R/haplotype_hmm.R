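#' Select informative SNPs
#'
#' A SNP is informative for founder-haplotype inference when all eight
#' founder alleles are observed (non-missing) and both alleles are present
#' among the founders (at least one founder carries the alternate allele and
#' at least one the reference allele).
#'
#' @param panel A `founder_panel`.
#' @return Logical mask over the panel SNPs.
#' @export
select_informative_snps <- function(panel) {
  a <- panel$alleles
  complete <- rowSums(is.na(a)) == 0
  s <- rowSums(a, na.rm = TRUE)
  complete & s >= 1 & s <= 7
}

#' HMM parameters for founder-haplotype inference
#'
#' @param emission_error Genotyping error rate epsilon in (0, 0.5): the
#'   probability that an observed call mismatches the donor founder's allele.
#' @param transition_rate Founder switch rate gamma per bp; the probability
#'   of staying in the same founder state across `d` bp is `exp(-gamma * d)`,
#'   with the leave mass split equally among the other seven founders.
#' @param prior Stationary prior over the 8 founder states.
#' @return List of class `"hmm_params"`.
#' @export
hmm_params <- function(emission_error = 0.002, transition_rate = 1e-7,
                       prior = rep(1 / 8, 8)) {
  if (emission_error <= 0 || emission_error >= 0.5)
    stop("emission_error must be in (0, 0.5)")
  if (transition_rate <= 0) stop("transition_rate must be > 0")
  stopifnot(length(prior) == 8, all(prior > 0))
  structure(list(emission_error = emission_error,
                 transition_rate = transition_rate,
                 prior = prior / sum(prior)),
            class = "hmm_params")
}

# Per-SNP emission matrix (snps x 8): P(call | founder state).
# Missing calls are uninformative (constant across states).
emission_matrix <- function(calls, alleles, eps) {
  n <- length(calls)
  E <- matrix(1, n, 8)
  obs <- !is.na(calls)
  match_mat <- alleles[obs, , drop = FALSE] == calls[obs]
  E[obs, ] <- ifelse(match_mat, 1 - eps, eps)
  E
}

#' Infer founder haplotype probabilities for one strain
#'
#' Runs a haploid eight-state hidden Markov model per chromosome over the
#' informative SNPs: emissions model symmetric genotyping error, transitions
#' follow a distance-dependent founder-switch kernel. Returns the
#' forward-backward posterior over founders at every informative SNP plus the
#' Viterbi maximum-a-posteriori state path. Chromosomes with no informative
#' SNPs get a uniform posterior with a warning.
#'
#' @param genotypes Integer vector of calls in `{0, 1, NA}` over panel SNPs,
#'   or a `mosaic_genome`.
#' @param panel A `founder_panel`.
#' @param params An [hmm_params()].
#' @param informative Logical mask (default [select_informative_snps()]).
#' @return Object of class `"haplotype_probs"`: list with `posterior` (SNPs x
#'   8 matrix, rows sum to 1), `map_path` (Viterbi founder index per SNP),
#'   `map` (chrom/pos of the retained SNPs), `loglik`.
#' @export
infer_haplotypes <- function(genotypes, panel, params = hmm_params(),
                             informative = select_informative_snps(panel)) {
  if (inherits(genotypes, "mosaic_genome")) genotypes <- genotypes$genotypes
  stopifnot(length(genotypes) == nrow(panel$map))
  keep <- which(informative)
  map <- panel$map[keep, , drop = FALSE]
  calls <- genotypes[keep]
  alleles <- panel$alleles[keep, , drop = FALSE]
  n <- length(keep)
  post <- matrix(NA_real_, n, 8)
  path <- integer(n)
  ll <- 0
  for (cn in unique(panel$map$chrom)) {
    idx <- which(map$chrom == cn)
    if (!length(idx)) {
      warning("chromosome ", cn, " has no informative SNPs")
      next
    }
    E <- emission_matrix(calls[idx], alleles[idx, , drop = FALSE],
                         params$emission_error)
    d <- diff(map$pos[idx])
    fb <- forward_backward8(E, d, params$transition_rate, params$prior)
    post[idx, ] <- fb$posterior
    path[idx] <- viterbi8(E, d, params$transition_rate, params$prior)
    ll <- ll + fb$loglik
  }
  if (any(is.na(post))) {
    # chromosomes without informative SNPs would leave gaps; none retained here
    post[is.na(post)] <- 1 / 8
  }
  colnames(post) <- panel$founder_ids
  structure(list(posterior = post, map_path = path, map = map, loglik = ll),
            class = "haplotype_probs")
}

# Scaled forward-backward over 8 founder states.
# E: n x 8 emissions; d: n-1 inter-SNP distances (bp); gamma: switch rate.
forward_backward8 <- function(E, d, gamma, prior) {
  n <- nrow(E)
  stay <- exp(-gamma * d)
  leave <- -expm1(-gamma * d) / 7
  alpha <- matrix(0, n, 8)
  scl <- numeric(n)
  a <- prior * E[1, ]
  scl[1] <- sum(a); alpha[1, ] <- a / scl[1]
  if (n > 1) for (t in 2:n) {
    # transition: stay*a + leave*(sum(a) - a)
    a <- (stay[t - 1] - leave[t - 1]) * alpha[t - 1, ] + leave[t - 1]
    a <- a * E[t, ]
    scl[t] <- sum(a); alpha[t, ] <- a / scl[t]
  }
  beta <- matrix(0, n, 8)
  beta[n, ] <- 1
  if (n > 1) for (t in (n - 1):1) {
    b <- beta[t + 1, ] * E[t + 1, ]
    beta[t, ] <- ((stay[t] - leave[t]) * b + leave[t] * sum(b)) / scl[t + 1]
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  list(posterior = post, loglik = sum(log(scl)))
}

# Log-space Viterbi over 8 founder states.
viterbi8 <- function(E, d, gamma, prior) {
  n <- nrow(E)
  logE <- log(E)
  lstay <- -gamma * d                               # log exp(-gamma d)
  lleave <- log(pmax(-expm1(-gamma * d) / 7, .Machine$double.xmin))
  delta <- log(prior) + logE[1, ]
  psi <- matrix(0L, n, 8)
  if (n > 1) for (t in 2:n) {
    leave_val <- delta + lleave[t - 1]
    o <- order(leave_val, decreasing = TRUE)
    nd <- numeric(8)
    for (k in 1:8) {
      stay_val <- delta[k] + lstay[t - 1]
      j <- if (o[1] != k) o[1] else o[2]            # best predecessor != k
      if (stay_val >= leave_val[j]) {
        nd[k] <- stay_val; psi[t, k] <- k
      } else {
        nd[k] <- leave_val[j]; psi[t, k] <- j
      }
    }
    delta <- nd + logE[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Founder dosage matrices for a strain cohort
#'
#' Stacks per-strain posterior founder probabilities into the loci x strains
#' x founders dosage array used by the genome scan. Dosages are the expected
#' haplotype contribution per founder (the posterior), not the MAP path.
#'
#' @param probs_list List of `haplotype_probs`, one per strain.
#' @return List: `dosages` (array loci x strains x 8), `map` (chrom/pos).
#' @export
founder_dosages <- function(probs_list) {
  stopifnot(length(probs_list) >= 1)
  map <- probs_list[[1]]$map
  n_loci <- nrow(map)
  n_strains <- length(probs_list)
  D <- array(NA_real_, c(n_loci, n_strains, 8))
  for (s in seq_len(n_strains)) {
    stopifnot(nrow(probs_list[[s]]$posterior) == n_loci)
    D[, s, ] <- probs_list[[s]]$posterior
  }
  dimnames(D) <- list(NULL, names(probs_list),
                      colnames(probs_list[[1]]$posterior))
  list(dosages = D, map = map)
}

#' MAP haplotype intervals in BED-like form
#'
#' Collapses a strain's Viterbi path into contiguous founder intervals
#' (chrom, start, end, founder), with boundaries at midpoints between SNPs
#' where the founder changes.
#'
#' @param probs A `haplotype_probs`.
#' @return data.frame `chrom`, `start`, `end`, `founder`.
#' @export
map_path_intervals <- function(probs) {
  map <- probs$map; path <- probs$map_path
  out <- list()
  for (cn in unique(map$chrom)) {
    idx <- which(map$chrom == cn)
    p <- path[idx]; pos <- map$pos[idx]
    brk <- which(diff(p) != 0)
    starts <- c(pos[1], (pos[brk] + pos[brk + 1]) / 2)
    ends <- c((pos[brk] + pos[brk + 1]) / 2, pos[length(pos)])
    out[[cn]] <- data.frame(chrom = cn, start = starts, end = ends,
                            founder = p[c(1, brk + 1)])
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
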