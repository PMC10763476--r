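#' Haplotype phasing by EM over population haplotype frequencies
#'
#' Reconstructs diplotypes for a short region by maximum likelihood: all
#' diplotypes compatible with each unphased genotype are enumerated, and
#' population haplotype frequencies are fitted by EM assuming random pairing.
#' Missing genotypes are marginalised by enumerating both alleles on both
#' haplotypes. Each individual is assigned the maximum-a-posteriori diplotype
#' under the final frequencies together with its posterior probability.
#'
#' The log-likelihood is asserted non-decreasing at every iteration, and the
#' fitted frequencies sum to 1 within 1e-9.
#'
#' @param genotypes N x L matrix over \{0,1,2,NA\} (alt-allele copies).
#'   Regions wider than `max_sites` are refused: the enumeration is
#'   exponential, window the region instead.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   log-likelihood (defaults 500 and 1e-8).
#' @param seed seed for the tiny jitter that breaks ties in the uniform
#'   initialisation.
#' @param max_sites enumeration width limit (default 25).
#' @return an object of class `PhasedSet`: a list with `individuals` (each a
#'   list `hap1`, `hap2`, `posterior`), `freqs` (named haplotype frequency
#'   estimates), `loglik` (trace) and `n_iter`.
#' @export
phase_em <- function(genotypes, max_iter = 500L, tol = 1e-8, seed = 1L,
                     max_sites = 25L) {
  genotypes <- as.matrix(genotypes)
  N <- nrow(genotypes); L <- ncol(genotypes)
  if (L > max_sites)
    stop("region too wide for diplotype enumeration (", L, " sites > ",
         max_sites, "); phase in windows instead")

  # Enumerate compatible ordered haplotype pairs per individual.
  hap_key <- character(0)
  hap_env <- new.env(hash = TRUE, parent = emptyenv())
  hap_index <- function(keys) {
    new <- keys[!vapply(keys, exists, logical(1), envir = hap_env)]
    for (k in unique(new)) {
      hap_key[[length(hap_key) + 1L]] <<- k
      assign(k, length(hap_key), envir = hap_env)
    }
    vapply(keys, get, integer(1) + 0L, envir = hap_env)
  }
  IA <- integer(0); IB <- integer(0); IND <- integer(0)
  for (i in seq_len(N)) {
    g <- genotypes[i, ]
    het <- which(!is.na(g) & g == 1L)
    mis <- which(is.na(g))
    n_pairs <- 2^length(het) * 4^length(mis)
    if (n_pairs > 2^16)
      stop("region too wide for diplotype enumeration (individual ", i,
           " expands to ", n_pairs, " diplotypes); phase in windows instead")
    base <- ifelse(is.na(g), 0L, as.integer(g %/% 2L))
    h1 <- matrix(base, nrow = n_pairs, ncol = L, byrow = TRUE)
    h2 <- h1
    bits <- function(n, width) {
      if (width == 0) return(matrix(integer(0), nrow = n, ncol = 0))
      m <- matrix(0L, n, width)
      v <- seq_len(n) - 1L
      for (b in seq_len(width)) { m[, b] <- v %% 2L; v <- v %/% 2L }
      m
    }
    conf <- bits(n_pairs, length(het) + 2 * length(mis))
    cpos <- 0L
    for (s in het) {
      cpos <- cpos + 1L
      h1[, s] <- conf[, cpos]; h2[, s] <- 1L - conf[, cpos]
    }
    for (s in mis) {
      h1[, s] <- conf[, cpos + 1L]; h2[, s] <- conf[, cpos + 2L]
      cpos <- cpos + 2L
    }
    ka <- apply(h1, 1, paste, collapse = "")
    kb <- apply(h2, 1, paste, collapse = "")
    IA <- c(IA, hap_index(ka)); IB <- c(IB, hap_index(kb))
    IND <- c(IND, rep.int(i, n_pairs))
  }
  H <- length(hap_key)

  f <- with_seed(seed, {
    j <- rep(1 / H, H) + runif(H) * 1e-6
    j / sum(j)
  })
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    w <- f[IA] * f[IB]
    Li <- as.vector(rowsum(w, IND))
    ll <- sum(log(Li))
    if (ll < ll_prev - 1e-9) stop("EM log-likelihood decreased")  # invariant
    ll_trace <- c(ll_trace, ll)
    post <- w / Li[IND]
    cnt <- numeric(H)
    agg <- rowsum(c(post, post), c(IA, IB))
    cnt[as.integer(rownames(agg))] <- agg[, 1]
    f <- cnt / (2 * N)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) break
    ll_prev <- ll
  }
  stopifnot(abs(sum(f) - 1) < 1e-9)

  # MAP diplotype per individual under the final frequencies; the posterior of
  # an unordered pair sums its two orders.
  individuals <- vector("list", N)
  to_vec <- function(k) as.integer(strsplit(k, "")[[1]])
  for (i in seq_len(N)) {
    sel <- IND == i
    ia <- IA[sel]; ib <- IB[sel]
    w <- f[ia] * f[ib]
    post <- w / sum(w)
    key <- paste(pmin(ia, ib), pmax(ia, ib))
    agg <- rowsum(post, key)
    best <- rownames(agg)[which.max(agg)]
    pr <- max(agg)
    pair <- as.integer(strsplit(best, " ")[[1]])
    individuals[[i]] <- list(hap1 = to_vec(hap_key[pair[1]]),
                             hap2 = to_vec(hap_key[pair[2]]),
                             posterior = min(1, pr))
  }
  names(f) <- hap_key
  structure(list(individuals = individuals, freqs = sort(f, decreasing = TRUE),
                 loglik = ll_trace, n_iter = length(ll_trace)),
            class = "PhasedSet")
}

#' @export
print.PhasedSet <- function(x, ...) {
  cat(sprintf("PhasedSet: %d individuals, %d candidate haplotypes, %d EM iterations\n",
              length(x$individuals), length(x$freqs), x$n_iter))
  invisible(x)
}

#' Drop poorly phased individuals
#'
#' Removes individuals whose maximum-a-posteriori diplotype has posterior
#' probability strictly below `min_posterior` (the boundary is kept).
#'
#' @param individuals the `individuals` element of a [phase_em()] result (or
#'   the `PhasedSet` itself).
#' @param min_posterior exclusion threshold (default 0.9).
#' @return list with `retained` (the surviving individuals), `kept` (their
#'   indices) and `n_excluded`.
#' @export
filter_phased <- function(individuals, min_posterior = 0.9) {
  if (inherits(individuals, "PhasedSet")) individuals <- individuals$individuals
  post <- vapply(individuals, `[[`, numeric(1), "posterior")
  keep <- post >= min_posterior
  list(retained = individuals[keep], kept = which(keep),
       n_excluded = sum(!keep))
}

#' Collect retained phased haplotypes into a panel
#'
#' @param phased a [phase_em()] result.
#' @param sites site metadata for the phased region.
#' @param min_posterior exclusion threshold passed to [filter_phased()].
#' @return a [haplotype_panel()] with two rows per retained individual and an
#'   `n_excluded` attribute.
#' @export
phased_to_panel <- function(phased, sites, min_posterior = 0.9) {
  fl <- filter_phased(phased, min_posterior)
  haps <- do.call(rbind, lapply(fl$retained, function(x) rbind(x$hap1, x$hap2)))
  panel <- haplotype_panel(haps, sites,
                           labels = rep(sprintf("ind%03d", fl$kept), each = 2))
  attr(panel, "n_excluded") <- fl$n_excluded
  panel
}
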