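# Compatibility validation, trait coverage and the two consortium solvers.

nine_compat <- ref_compatibility()

test_that("consortium validity forbids antagonistic and limited-growth pairs", {
  bad <- validate_consortium(c("UC4521", "UC4450"), nine_compat)
  expect_false(bad$valid)
  expect_equal(bad$violations$outcome, "antagonistic")
  lim <- validate_consortium(c("UC4510", "UC4535"), nine_compat)
  expect_false(lim$valid)
  expect_equal(lim$violations$outcome, "limited_growth")
  expect_true(validate_consortium("UC4449", nine_compat)$valid)
  expect_true(validate_consortium(c("UC4449", "UC4450", "UC4490"),
                                  nine_compat)$valid)
  expect_error(validate_consortium(c("UC4449", "STRANGER"), nine_compat),
               class = "rr_incomplete_matrix")
})

test_that("compatibility matrices are symmetric with canonical storage", {
  m <- compatibility_matrix(data.frame(
    strain_a = c("B", "A", "C"), strain_b = c("A", "C", "C"),
    outcome = c("antagonistic", "compatible", "compatible")))
  expect_equal(nrow(m), 2)  # self-pair dropped
  expect_equal(pair_outcome(m, "A", "B"), pair_outcome(m, "B", "A"))
  expect_error(compatibility_matrix(data.frame(
    strain_a = c("A", "B"), strain_b = c("B", "A"),
    outcome = c("compatible", "antagonistic"))),
    class = "rr_invalid_input")
})

test_that("trait coverage is the union of members' level-5 traits", {
  sc <- data.frame(strain_id = c("m1", "m2"),
                   A = c(1, 0), B = c(1, 1), C = c(0.75, 1))
  expect_equal(trait_coverage(character(0), sc), character(0))
  expect_equal(trait_coverage("m1", sc), c("A", "B"))
  expect_equal(trait_coverage(c("m1", "m2"), sc), c("A", "B", "C"))
  # threshold is configurable
  expect_equal(trait_coverage("m1", sc, threshold = 0.75), c("A", "B", "C"))
  expect_error(trait_coverage("nope", sc), class = "rr_lookup_error")
})

test_that("coverage is monotone under adding a compatible member", {
  set.seed(9)
  for (i in 1:20) {
    inst <- random_consortium_instance(6, 5, p_bad = 0, seed = i)
    members <- sample(inst$ids, 3)
    extra <- setdiff(inst$ids, members)[1]
    expect_true(all(trait_coverage(members, inst$scores) %in%
                      trait_coverage(c(members, extra), inst$scores)))
  }
})

test_that("assembly separates a planted antagonistic pair", {
  # four strains with disjoint level-5 traits; (a, b) antagonistic
  sc <- data.frame(strain_id = c("a", "b", "c", "d"),
                   T1 = c(1, 0, 0, 0), T2 = c(0, 1, 0, 0),
                   T3 = c(0, 0, 1, 0), T4 = c(0, 0, 0, 1))
  pr <- utils::combn(c("a", "b", "c", "d"), 2)
  cm <- compatibility_matrix(data.frame(
    strain_a = pr[1, ], strain_b = pr[2, ],
    outcome = ifelse(pr[1, ] == "a" & pr[2, ] == "b", "antagonistic",
                     "compatible")))
  for (method in c("greedy", "exact")) {
    plans <- assemble_consortia(c("a", "b", "c", "d"), sc, cm,
                                n_consortia = 2, size_range = c(2, 2),
                                method = method)
    for (p in plans) {
      expect_false(all(c("a", "b") %in% p$members))
      expect_true(validate_consortium(p$members, cm)$valid)
      expect_equal(p$coverage_count, 2)
    }
  }
  expect_equal(assemble_consortia(c("a", "b"), sc, cm, n_consortia = 0),
               list())
})

test_that("assembly from the nine reference strains respects all constraints", {
  tab <- ref_score_table()
  sel <- tab$strain_id[tab$selected]
  scores <- tab[, c("strain_id", names(tab)[3:12])]
  for (method in c("greedy", "exact")) {
    plans <- assemble_consortia(sel, scores, nine_compat, n_consortia = 4,
                                size_range = c(2, 4), method = method)
    expect_gte(length(plans), 1)
    for (p in plans) {
      expect_true(validate_consortium(p$members, nine_compat)$valid)
      expect_false(all(c("UC4521", "UC4450") %in% p$members))
      expect_false(all(c("UC4510", "UC4535") %in% p$members))
    }
  }
})

test_that("exact mode matches the brute-force optimum on random instances", {
  for (seed in 1:30) {
    inst <- random_consortium_instance(n_strains = 7, n_traits = 6,
                                       p_bad = 0.2, seed = seed)
    best <- tryCatch(
      assemble_consortia(inst$ids, inst$scores, inst$compat,
                         n_consortia = 1, size_range = c(2, 4),
                         method = "exact")[[1]]$coverage_count,
      rr_infeasible = function(e) NA)
    oracle <- brute_force_best_coverage(inst$ids, inst$scores, inst$compat,
                                        c(2, 4))
    if (is.na(best)) {
      expect_identical(oracle, -Inf)
    } else {
      expect_equal(best, oracle)
    }
  }
})

test_that("greedy achieves at least (1 - 1/e) of the exact optimum", {
  ratio_ok <- 0L; n_run <- 0L
  for (seed in 1:60) {
    inst <- random_consortium_instance(n_strains = 8, n_traits = 8,
                                       p_bad = 0.15, seed = 1000 + seed)
    exact <- tryCatch(
      assemble_consortia(inst$ids, inst$scores, inst$compat,
                         n_consortia = 1, size_range = c(2, 4),
                         method = "exact")[[1]]$coverage_count,
      rr_infeasible = function(e) NA)
    if (is.na(exact) || exact == 0) next
    greedy <- assemble_consortia(inst$ids, inst$scores, inst$compat,
                                 n_consortia = 1, size_range = c(2, 4),
                                 method = "greedy")[[1]]$coverage_count
    n_run <- n_run + 1L
    if (greedy >= (1 - exp(-1)) * exact) ratio_ok <- ratio_ok + 1L
  }
  expect_gte(n_run, 30)
  expect_equal(ratio_ok, n_run)
})

test_that("fully antagonistic pools make multi-member designs infeasible", {
  ids <- c("x", "y", "z")
  cm <- generate_compatibility(ids, p_antagonism = 1, p_limited = 0, seed = 5)
  sc <- data.frame(strain_id = ids, T1 = c(1, 1, 1))
  expect_error(assemble_consortia(ids, sc, cm, n_consortia = 1,
                                  size_range = c(2, 3)),
               class = "rr_infeasible")
})
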