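# Independent oracles used to validate the package's computations.
# These deliberately re-derive each quantity from first principles and share
# no code with the implementation paths they check.

AA20_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(len) paste(sample(AA20_TEST, len, replace = TRUE),
                                  collapse = "")

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
})

# full-matrix Gotoh dynamic programme, affine gaps (cost open + k*extend),
# end gaps penalised; returns only the optimal score
oracle_align_score <- function(a, b, S = blosum62, open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n > 0) for (i in 2:(n + 1)) Ix[i, 1] <- -open - (i - 1) * ext
  if (m > 0) for (j in 2:(m + 1)) Iy[1, j] <- -open - (j - 1) * ext
  if (n > 0 && m > 0) for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) +
      S[A[i - 1], B[j - 1]]
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext,
                    Iy[i - 1, j] - open - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext,
                    Ix[i, j - 1] - open - ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, point probabilities from binomial coefficients (not dhyper)
oracle_fisher_p <- function(a, b, c, d) {
  N <- a + b + c + d
  row1 <- a + b; col1 <- a + c
  ks <- max(0, row1 + col1 - N):min(row1, col1)
  prob <- vapply(ks, function(k) {
    exp(lchoose(col1, k) + lchoose(N - col1, row1 - k) - lchoose(N, row1))
  }, numeric(1))
  p_obs <- prob[ks == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Welch statistic and p-value from first principles; the t tail probability
# comes through the regularised incomplete beta function, not pt()
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- stats::pbeta(df / (df + t^2), df / 2, 1 / 2)
  list(t = t, df = df, p = p)
}

# tiny ready-made simulation configuration for fast pipeline-level tests
small_sim_config <- function(...) {
  defaults <- list(seed = 7, n_degraders = 3L, n_nondegraders = 3L,
                   genes_per_strain = 30L, protein_length = 60L,
                   cluster_size = 5L, cluster_start_rank = 11L,
                   background_divergence = 0,
                   cluster_divergence_degraders = 0,
                   cluster_loss_prob = 1, mean_count = 1000,
                   nb_dispersion = 0.05, growth_replicates = 4L,
                   growth_t_max = 36, growth_dt = 1)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
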