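test_that("composition tabulation builds consistent margins", {
  types <- c(rep("T1", 30), rep("T2", 70))
  cond <- c(rep("trt", 10), rep("ctl", 20), rep("trt", 30), rep("ctl", 40))
  tab <- tabulate_composition(types, cond, conditions = c("trt", "ctl"))
  expect_equal(tab$m, 40)
  expect_equal(tab$n, 60)
  expect_equal(unname(tab$k), c(30, 70))
  expect_equal(unname(tab$q), c(10, 30))
  expect_true(all(tab$q <= tab$k & tab$q <= tab$m))

  # permuting cells leaves the table unchanged
  perm <- withr::with_seed(5, sample(100))
  tab2 <- tabulate_composition(types[perm], cond[perm],
                               conditions = c("trt", "ctl"))
  expect_identical(tab2$counts, tab$counts)
  expect_error(tabulate_composition(character(), character()), "empty")
  expect_error(tabulate_composition(c("a", NA), c("x", "y")), "unlabeled")
})

test_that("hypergeometric tails equal subset enumeration (N <= 12)", {
  for (N in c(6, 9, 12)) {
    for (K in c(2, floor(N / 2))) {
      for (nd in c(2, floor(N / 2), N - 1)) {
        for (q in 0:min(K, nd)) {
          for (tl in c("lower", "upper")) {
            expect_equal(hypergeom_tail(q, K, N, nd, tl),
                         enum_hyper_tail(q, K, N, nd, tl),
                         tolerance = 1e-12,
                         info = sprintf("q=%d K=%d N=%d n=%d %s", q, K, N,
                                        nd, tl))
          }
        }
      }
    }
  }
  expect_equal(hypergeom_tail(5, 5, 10, 5, "upper"), 1 / 252,
               tolerance = 1e-15)
  # full support and complementarity
  expect_equal(hypergeom_tail(4, 6, 12, 4, "lower"), 1)
  for (q in 0:3)
    expect_equal(hypergeom_tail(q, 4, 10, 4, "lower") +
                   hypergeom_tail(q + 1, 4, 10, 4, "upper"), 1,
                 tolerance = 1e-12)
  expect_error(hypergeom_tail(3, 12, 10, 5), "inconsistent")
})

test_that("abundance shift test: arithmetic, symmetry, fisher cross-check", {
  mk_tab <- function(a, b, c_, d) {
    tabulate_composition(c(rep("C", a + b), rep("rest", c_ + d)),
                         c(rep("A", a), rep("B", b), rep("A", c_),
                           rep("B", d)),
                         conditions = c("A", "B"))
  }
  bal <- abundance_shift_test(mk_tab(10, 10, 10, 10), "C")
  expect_equal(bal$odds_ratio, 1)
  expect_equal(bal$p_value, 1)

  r <- abundance_shift_test(mk_tab(20, 10, 10, 20), "C")
  expect_equal(r$odds_ratio, 4)
  expect_true(r$ci_low < 4 && 4 < r$ci_high)

  # label symmetry: swapping conditions inverts OR and CI, keeps p
  r_sw <- abundance_shift_test(
    tabulate_composition(c(rep("C", 30), rep("rest", 30)),
                         c(rep("B", 20), rep("A", 10), rep("B", 10),
                           rep("A", 20)),
                         conditions = c("A", "B")), "C")
  expect_equal(r_sw$odds_ratio, 1 / r$odds_ratio, tolerance = 1e-12)
  expect_equal(r_sw$ci_low, 1 / r$ci_high, tolerance = 1e-6)
  expect_equal(r_sw$ci_high, 1 / r$ci_low, tolerance = 1e-6)
  expect_equal(r_sw$p_value, r$p_value, tolerance = 1e-12)

  # two-sided p >= one-sided tails' minimum; complement relabeling keeps p
  expect_gte(r$p_value, min(r$p_lower, r$p_upper) - 1e-12)
  r_c <- abundance_shift_test(mk_tab(10, 20, 20, 10), "C")
  expect_equal(r_c$p_value, r$p_value, tolerance = 1e-12)

  # independent route: fisher.test agrees on p and CI
  ft <- stats::fisher.test(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r$p_value, ft$p.value, tolerance = 1e-9)
  expect_equal(r$ci_low, ft$conf.int[1], tolerance = 1e-4)
  expect_equal(r$ci_high, ft$conf.int[2], tolerance = 1e-4)

  # Haldane flag on zero cells
  rz <- abundance_shift_test(mk_tab(5, 0, 10, 10), "C")
  expect_true(rz$haldane_corrected)
  expect_error(abundance_shift_test(mk_tab(1, 1, 1, 1), "missing"),
               "not in table")
})

test_that("overlap test matches the shared enumeration and edge cases", {
  U <- sprintf("u%d", 1:10)
  A <- U[1:5]
  r_eq <- overlap_test(A, A, U)
  expect_equal(r_eq$overlap, 5)
  expect_equal(r_eq$p_enrichment, 1 / 252, tolerance = 1e-15)
  r_dis <- overlap_test(A, U[6:10], U)
  expect_equal(r_dis$overlap, 0)
  expect_equal(r_dis$p_enrichment, 1)
  expect_equal(r_dis$expected, 2.5)
  # two-sided equals enumeration on a random small urn
  r2 <- overlap_test(U[1:4], U[3:8], U)
  expect_equal(r2$p_two_sided, enum_hyper_twosided(2, 4, 10, 6),
               tolerance = 1e-12)
  expect_error(overlap_test(c(A, "zzz"), A, U), "subsets")
})

test_that("exact conditional CIs reach nominal coverage at OR = 1", {
  set.seed(50)
  n_reps <- 300
  cover <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    q <- rbinom(1, 200, 0.15)
    kq <- rbinom(1, 200, 0.15)
    tab <- tabulate_composition(
      c(rep("C", q + kq), rep("rest", 400 - q - kq)),
      c(rep("A", q), rep("B", kq), rep("A", 200 - q), rep("B", 200 - kq)),
      conditions = c("A", "B"))
    r <- abundance_shift_test(tab, "C")
    cover[i] <- r$ci_low <= 1 && 1 <= r$ci_high
  }
  expect_gte(mean(cover), 0.94)
})
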