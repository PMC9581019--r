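test_that("hypergeometric tails are exact: worked example and oracle sweep", {
  universe <- sprintf("g%d", 1:20)
  term <- universe[1:10]
  module <- universe[1:5]            # module entirely inside the term
  res <- hypergeom_test(module, term, universe, "over")
  expect_equal(res$p_value, 252 / 15504, tolerance = 1e-12)
  expect_equal(res$p_value, 0.016254, tolerance = 1e-5)
  expect_identical(res$overlap, 5L)

  # k = n with direction under -> the full lower tail is 1
  expect_equal(hypergeom_test(module, term, universe, "under")$p_value, 1,
               tolerance = 1e-15)

  # full enumeration against the combinatorial-sum oracle for modest N,
  # random draws up to N = 60; results collected and compared in bulk
  got_over <- got_under <- exp_over <- exp_under <- ident <- numeric(0)
  run_case <- function(N, K, n_mod, k) {
    uni <- sprintf("u%d", 1:N)
    mod <- c(uni[seq_len(k)], if (n_mod > k) uni[(K + 1):(K + n_mod - k)])
    trm <- uni[seq_len(K)]
    over <- hypergeom_test(mod, trm, uni, "over")$p_value
    under <- hypergeom_test(mod, trm, uni, "under")$p_value
    got_over <<- c(got_over, over); got_under <<- c(got_under, under)
    exp_over <<- c(exp_over, hyper_oracle(N, K, n_mod, k, "over"))
    exp_under <<- c(exp_under, hyper_oracle(N, K, n_mod, k, "under"))
    ident <<- c(ident, over + under - stats::dhyper(k, K, N - K, n_mod))
  }
  for (N in c(5L, 9L, 13L)) {
    for (K in 0:N) for (n_mod in 1:N) {
      for (k in max(0L, n_mod + K - N):min(n_mod, K)) run_case(N, K, n_mod, k)
    }
  }
  set.seed(41)
  for (rep in 1:200) {
    N <- sample(14:60, 1)
    K <- sample(0:N, 1)
    n_mod <- sample(1:N, 1)
    kr <- max(0L, n_mod + K - N):min(n_mod, K)
    k <- kr[sample.int(length(kr), 1)]
    run_case(N, K, n_mod, k)
  }
  expect_equal(got_over, exp_over, tolerance = 1e-12)
  expect_equal(got_under, exp_under, tolerance = 1e-12)
  expect_equal(ident, rep(1, length(ident)), tolerance = 1e-12)
})

test_that("hypergeometric preconditions are enforced", {
  expect_error(hypergeom_test("g1", "g1", character(0)), "empty")
  expect_error(hypergeom_test(character(0), "g1", "g1"), "empty")
  expect_error(hypergeom_test("gX", "g1", c("g1", "g2")), "subset")
})

test_that("enrich_module runs all six batteries and pools results", {
  df <- data.frame(
    term = rep(c("B1", "B2", "C1", "M1"), times = c(2, 2, 2, 2)),
    namespace = rep(c("BP", "BP", "CC", "MF"), times = c(2, 2, 2, 2)),
    gene = c("g1", "g2", "g3", "g4", "g1", "g5", "g2", "g6"))
  anno <- annotation_map(df)
  uni <- sprintf("g%d", 1:10)
  res <- enrich_module(c("g1", "g2", "g3"), anno, uni)
  expect_identical(nrow(res), 8L)               # 4 terms x 2 directions
  expect_setequal(unique(res$direction), c("over", "under"))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(!is.unsorted(res$p_value))

  expect_error(enrich_module(c("gX"), anno, uni), "no genes in the universe")
  away <- annotation_map(data.frame(term = "T", namespace = "BP", gene = "zz"))
  expect_error(enrich_module(c("g1"), away, uni), "no genes")
})

test_that("module quality follows the negative-log geometric mean closed form", {
  mk <- function(p) data.frame(term = sprintf("t%d", seq_along(p)),
                               direction = "over", p_value = p)
  expect_equal(module_quality(mk(rep(1e-3, 5)))$Q, 3, tolerance = 1e-12)
  expect_equal(module_quality(mk(10^-(2:6)))$Q, 4, tolerance = 1e-12)

  # only the five smallest survive; removing the larger extras changes nothing
  seven <- mk(c(10^-(2:6), 0.5, 0.9))
  expect_equal(module_quality(seven)$Q, 4, tolerance = 1e-12)
  expect_identical(nrow(module_quality(seven)$top), 5L)
  expect_false(module_quality(seven)$fewer_than_five)

  short <- module_quality(mk(c(1e-2, 1e-4)))
  expect_true(short$fewer_than_five)
  expect_equal(short$Q, 3, tolerance = 1e-12)    # divisor adapts to count

  # deterministic tie-break by term id
  tied <- data.frame(term = c("zz", "aa", "mm"), direction = "over",
                     p_value = c(0.01, 0.01, 0.01))
  expect_identical(module_quality(tied)$top$term, c("aa", "mm", "zz"))
})

test_that("pipeline quality averages module qualities", {
  expect_equal(pipeline_quality(4), 4)
  expect_equal(pipeline_quality(c(2, 4)), 3)
  expect_equal(pipeline_quality(c(4, 2)), pipeline_quality(c(2, 4)))
  expect_error(pipeline_quality(numeric(0)), "at least one")
})

test_that("top-term overlap counts shared term ids of the best modules", {
  mk_report <- function(terms, Q = 5) {
    structure(list(modules = list(list(
      label = 1L, size = 40L, Q = Q,
      top = data.frame(term = terms, namespace = "BP", direction = "over",
                       p_value = 1e-6), fewer_than_five = FALSE)),
      Q_bar = Q, n_modules = 1L, pct_unassigned = 0),
      class = "ModuleQualityReport")
  }
  a <- mk_report(sprintf("T%d", 1:5))
  expect_identical(compare_top_terms(a, a), 5L)
  expect_identical(compare_top_terms(a, mk_report(sprintf("X%d", 1:5))), 0L)
  expect_identical(compare_top_terms(a, mk_report(c("T1", "T2", "X1", "X2", "X3"))), 2L)
})

test_that("clustering summary reports counts and unassigned percentages", {
  genes <- sprintf("g%d", 1:100)
  a <- stats::setNames(c(rep(1:3, times = c(40, 30, 12)), rep(0L, 18)), genes)
  b <- stats::setNames(rep(c(1L, 2L), each = 50), genes)
  z <- stats::setNames(rep(0L, 100), genes)
  s <- clustering_summary(list(one = a, two = b, none = z))
  expect_identical(s$n_modules, c(3L, 2L, 0L))
  expect_identical(s$pct_unassigned, c(18, 0, 100))
  expect_error(clustering_summary(list(b = b, bad = stats::setNames(
    rep(1L, 3), c("x", "y", "z")))), "universe")
})
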