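# Independent oracles and small shared fixtures, built in code.

# exhaustive-enumeration Fisher oracle over all tables with the observed
# margins, using base R's dhyper (independent of the package kernel)
oracle_fisher_p <- function(a, b, c, d) {
  N <- a + b + c + d
  r <- a + b
  k <- a + c
  s <- max(0, r + k - N):min(r, k)
  pmf <- dhyper(s, k, N - k, r)
  obs <- dhyper(a, k, N - k, r)
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

# literal BH definition, O(n^2): q_(i) = min_{j>=i} p_(j) * n / j
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    j <- i:n
    q[i] <- min(1, min(ps[j] * n / j))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# small two-component read set on the packaged fixture
tiny_read_sim <- function(n = 50, seed = 421, ...) {
  design <- make_tsdr_fixture()
  sim <- simulate_bisulfite_reads(
    design, n_reads = n,
    components = list(list(weight = 0.5, p = 0),
                      list(weight = 0.5, p = 1)),
    seed = seed, ...)
  list(design = design, sim = sim)
}

# compact manifest + beta matrix with a planted hypo set
tiny_array_sim <- function(n_probes = 800, n_planted = 40, delta = -0.5,
                           noise_sd = 0.02, seed = 99) {
  manifest <- simulate_probe_manifest(n_probes = n_probes, n_chrom = 4,
                                      seed = seed)
  planted <- withr::with_seed(seed + 1, tibble::tibble(
    probe_id = sample(manifest$probe_id, n_planted),
    group = "treat", delta = delta))
  sim <- simulate_beta_matrix(manifest, groups = c(ctrl = 3, treat = 3),
                              planted = planted, noise_sd = noise_sd,
                              seed = seed + 2)
  list(manifest = manifest, planted = planted, sim = sim)
}
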