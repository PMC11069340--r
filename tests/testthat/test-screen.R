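toy_cons <- function(id_deg, id_non, cov_deg = 100, cov_non = 100) {
  rbind(
    data.frame(gene_id = "g1", strain_id = c("D1", "D2"),
               identity_pct = id_deg, coverage_pct = cov_deg,
               best_hit_locus = "x"),
    data.frame(gene_id = "g1", strain_id = c("N1", "N2"),
               identity_pct = id_non, coverage_pct = cov_non,
               best_hit_locus = "y"))
}
toy_ph <- data.frame(strain_id = c("D1", "D2", "N1", "N2"),
                     degrader = c(TRUE, TRUE, FALSE, FALSE),
                     isolation_source = "soil")

test_that("candidate classification intersects all three criteria", {
  fc_up <- data.frame(gene_id = "g1", log2fc = 2)
  fc_dn <- data.frame(gene_id = "g1", log2fc = 0)

  # conserved in degraders, absent in non-degraders -> candidate
  cons <- toy_cons(id_deg = 100, id_non = NA)
  res <- classify_candidates(fc_up, cons, toy_ph)
  expect_true(res$candidate)
  expect_equal(res$frac_conserved_degraders, 1)
  expect_equal(res$frac_nonconserved_nondegraders, 1)

  # not upregulated -> never a candidate, whatever the conservation
  expect_false(classify_candidates(fc_dn, cons, toy_ph)$candidate)

  # conserved everywhere -> fails criterion (3)
  expect_false(classify_candidates(fc_up, toy_cons(100, 100), toy_ph)$candidate)

  # low coverage in a degrader -> fails criterion (2)
  expect_false(classify_candidates(
    fc_up, toy_cons(100, NA, cov_deg = c(30, 100)), toy_ph)$candidate)

  ph_onesided <- toy_ph[toy_ph$degrader, ]
  expect_error(classify_candidates(fc_up, cons, ph_onesided), "non-degrader")
})

test_that("relaxing the fold-change threshold never shrinks the candidate set", {
  cfg <- small_sim_config(seed = 17, background_divergence = 0.05)
  sim <- simulate_panel(cfg)
  cm <- simulate_counts(sim, cfg)
  fc <- log2_fold_change(cpm_normalize(cm), cm$design)
  cons <- conservation_matrix(sim$panel)
  prev <- character(0)
  for (thr in c(3, 2, 1, 0, -1)) {
    cand <- classify_candidates(fc, cons, sim$panel$phenotypes,
                                screen_criteria(log2fc_threshold = thr),
                                reference_strain_id = "REF")
    ids <- cand$gene_id[cand$candidate]
    expect_true(all(prev %in% ids))
    prev <- ids
  }
})

test_that("hotspot detection finds maximal gap-tolerant runs", {
  flags <- function(x) data.frame(replicon_id = "c", rank = seq_along(x),
                                  locus_id = sprintf("L%02d", seq_along(x)),
                                  candidate = as.logical(x))
  hs <- find_hotspots(flags(rep(1, 6)), min_run = 2, max_gap = 1)
  expect_length(hs, 1)
  expect_equal(hs[[1]]$start_rank, 1)
  expect_equal(hs[[1]]$end_rank, 6)

  expect_length(find_hotspots(flags(rep(0, 6)), min_run = 1, max_gap = 1), 0)

  # enumerated by hand: candidates at 1,2,4,5 form one run (gap 1 allowed),
  # the trailing singleton at 9 is below min_run
  hs <- find_hotspots(flags(c(1, 1, 0, 1, 1, 0, 0, 0, 1)),
                      min_run = 3, max_gap = 1)
  expect_length(hs, 1)
  expect_equal(hs[[1]]$start_rank, 1)
  expect_equal(hs[[1]]$end_rank, 5)
  expect_equal(hs[[1]]$n_candidates, 4)
  expect_equal(hs[[1]]$locus_ids, c("L01", "L02", "L04", "L05"))
  expect_equal(hs[[1]]$span, 5)

  expect_error(find_hotspots(flags(c(1, 0)), min_run = 0), "min_run")
})

test_that("hotspots mirror under gene-order reversal", {
  set.seed(41)
  for (i in 1:20) {
    x <- stats::runif(30) < 0.3
    fwd <- find_hotspots(data.frame(replicon_id = "c", rank = 1:30,
                                    locus_id = sprintf("L%02d", 1:30),
                                    candidate = x),
                         min_run = 3, max_gap = 2)
    rev_ <- find_hotspots(data.frame(replicon_id = "c", rank = 1:30,
                                     locus_id = sprintf("L%02d", 30:1),
                                     candidate = rev(x)),
                          min_run = 3, max_gap = 2)
    expect_equal(length(fwd), length(rev_))
    fwd_sets <- lapply(fwd, function(h) sort(h$locus_ids))
    rev_sets <- lapply(rev_, function(h) sort(h$locus_ids))
    expect_setequal(fwd_sets, rev_sets)
  }
})

test_that("Fisher p-values match exact enumeration", {
  expect_equal(fisher_exact_2x2(c(1, 1, 1, 1))$p_two_sided, 1)
  # [[3,0],[0,3]]: C(6,3) = 20 tables, extremes a=0 and a=3 each 1/20
  expect_equal(fisher_exact_2x2(c(3, 0, 0, 3))$p_two_sided, 0.1)
  expect_equal(fisher_exact_2x2(c(5, 0, 0, 5))$p_two_sided, 2 / 252)
  expect_error(fisher_exact_2x2(c(-1, 1, 1, 1)), "non-negative")

  set.seed(51)
  for (i in 1:200) {
    tab <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    res <- fisher_exact_2x2(tab)
    expect_equal(res$p_two_sided,
                 oracle_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12, info = paste(tab, collapse = ","))
    # independent cross-check against the reference implementation
    expect_equal(res$p_two_sided,
                 stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Fisher p is invariant to transposition and simultaneous row/col swaps", {
  set.seed(52)
  for (i in 1:50) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)$p_two_sided
    expect_equal(fisher_exact_2x2(t(tab))$p_two_sided, p)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p_two_sided, p)
  }
})

test_that("odds ratio is the unconditioned cross-product with infinities", {
  expect_equal(fisher_exact_2x2(c(6, 2, 3, 4))$odds_ratio, 24 / 6)
  expect_equal(fisher_exact_2x2(c(5, 0, 0, 5))$odds_ratio, Inf)
})

test_that("trait enrichment builds the right table and handles degeneracy", {
  strains <- sprintf("s%02d", 1:10)
  presence <- stats::setNames(rep(c(TRUE, FALSE), each = 5), strains)
  res <- trait_enrichment(presence, presence)  # perfect co-occurrence
  expect_equal(unname(res$contingency), matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(res$p_two_sided, 2 / 252, tolerance = 1e-12)

  all_trait <- stats::setNames(rep(TRUE, 10), strains)
  expect_equal(trait_enrichment(presence, all_trait)$p_two_sided, 1)

  expect_error(trait_enrichment(presence, all_trait[1:5]), "same strains")
})

test_that("under independence the enrichment p-value is near-uniform", {
  set.seed(61)
  ps <- replicate(60, {
    strains <- sprintf("s%02d", 1:50)
    presence <- stats::setNames(sample(c(TRUE, FALSE), 50, replace = TRUE), strains)
    trait <- stats::setNames(sample(c(TRUE, FALSE), 50, replace = TRUE), strains)
    trait_enrichment(presence, trait)$p_two_sided
  })
  expect_gte(median(ps), 0.3)
})
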