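tiny_responses <- function(choices, group = "KR", consistent = TRUE) {
  n_q <- length(choices[[1]])
  do.call(rbind, lapply(seq_along(choices), function(i) {
    data.frame(participant_id = sprintf("%s%02d", group, i), group = group,
               question_id = seq_len(n_q), chosen_type = choices[[i]],
               assignment_consistent = consistent)
  })) |> response_set()
}

test_that("response_set enforces its structural invariants", {
  ok <- tiny_responses(list(rep("korean", 3), rep("english", 3)))
  expect_s3_class(ok, "response_set")
  dup <- as.data.frame(ok)[c(1, 1, 2), ]
  expect_error(response_set(dup), "duplicate")
  bad <- as.data.frame(ok); bad$chosen_type[1] <- "klingon"
  expect_error(response_set(bad), "chosen_type")
})

test_that("preference proportions count choices per group", {
  r <- tiny_responses(list(rep("korean", 10),
                           c(rep("korean", 2), rep("english", 5),
                             rep("chinese", 3)),
                           rep("english", 10)))
  p <- preference_proportions(r, "KR")
  expect_equal(sum(p), 1)
  expect_equal(unname(p["korean"]), 12 / 30)
  expect_equal(unname(p["english"]), 15 / 30)
  expect_equal(unname(p["chinese"]), 3 / 30)
  expect_error(preference_proportions(r, "UK"), "unknown group")
  solo <- tiny_responses(list(rep("korean", 5)))
  expect_equal(unname(preference_proportions(solo, "KR")),
               c(0, 0, 1))
})

test_that("intended rate equals the designated type's preference proportion", {
  set.seed(41)
  r <- simulate_responses(n_per_group = c(UK = 30, CN = 30, KR = 30),
                          weights = list(UK = c(0.5, 0.2, 0.3)), seed = 41)
  for (g in c("UK", "CN", "KR")) {
    des <- default_designation()
    expect_equal(unname(intended_rate(r, des)[g]),
                 unname(preference_proportions(r, g)[des[[g]]]))
  }
  expect_error(intended_rate(r, c(UK = "english")), "missing")
})

test_that("mapping consistency rate counts the follow-up assignments", {
  r <- tiny_responses(list(rep("korean", 5), rep("korean", 5)))
  expect_equal(mapping_consistency_rate(r), 1)
  df <- as.data.frame(r)
  df$assignment_consistent <- c(rep(TRUE, 7), rep(FALSE, 3))
  expect_equal(mapping_consistency_rate(response_set(df)), 0.7)
  df$assignment_consistent <- NA
  expect_error(mapping_consistency_rate(response_set(df)), "populated")
})

test_that("permutation null replicates are proportions with the right moments", {
  null1 <- permutation_null(5, 2, reps = 1, seed = 3)
  expect_equal(sum(null1$replicates), 1)
  null <- permutation_null(266, 10, reps = 10000, seed = 19)
  expect_equal(dim(null$replicates), c(10000, 3))
  expect_equal(rowSums(null$replicates), rep(1, 10000))
  expect_lt(max(abs(colMeans(null$replicates) - 1 / 3)), 0.001)
  sd_expect <- sqrt((1 / 3) * (2 / 3) / 2660)
  expect_lt(max(abs(apply(null$replicates, 2, sd) / sd_expect - 1)), 0.1)
  # reproducible from seed
  null2 <- permutation_null(266, 10, reps = 100, seed = 19)
  expect_identical(null2$replicates[1, ], null$replicates[1, ])
})

test_that("permutation p-values behave at chance and under strong effects", {
  null <- permutation_null(266, 10, reps = 10000, seed = 5)
  expect_gt(permutation_p_value(null, 1 / 3, "korean"), 0.9)
  expect_lt(permutation_p_value(null, 0.45, "korean"), 0.001)
  # smoothing keeps p away from zero
  expect_gte(permutation_p_value(null, 0.99, "english"), 1 / 10001)
  # ties count as extreme
  obs <- null$replicates[1, "english"]
  dev <- abs(null$replicates[, "english"] - 1 / 3)
  expect_equal(permutation_p_value(null, obs, "english"),
               (sum(dev >= abs(obs - 1 / 3)) + 1) / 10001)
})

test_that("uniform responding is rejected at close to the nominal level", {
  null <- permutation_null(266, 10, reps = 2000, seed = 77)
  set.seed(78)
  rejections <- replicate(1000, {
    obs <- rmultinom(1, 2660, rep(1 / 3, 3))[1] / 2660
    permutation_p_value(null, obs, "english") < 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("question preference vectors match hand counts and partition to one", {
  r <- tiny_responses(list(c("korean", "english", "korean"),
                           c("korean", "chinese", "english")))
  qm <- question_preference_matrix(r, c(KR = "korean"))
  expect_equal(dim(qm), c(4, 3))
  expect_equal(unname(qm["KR preferring korean", ]), c(1, 0, 0.5))
  expect_equal(unname(qm["KR preferring english", ]), c(0, 0.5, 0.5))
  # per question the three preference proportions sum to 1
  expect_equal(colSums(qm[1:3, ]), c(q1 = 1, q2 = 1, q3 = 1))
  # with all assignments consistent, intended equals preferring designated
  expect_equal(unname(qm["KR selecting korean (intended)", ]),
               unname(qm["KR preferring korean", ]))
  # flipping assignments empties the intended vector but not the preference
  df <- as.data.frame(r); df$assignment_consistent <- FALSE
  qm2 <- question_preference_matrix(response_set(df), c(KR = "korean"))
  expect_equal(unname(qm2["KR selecting korean (intended)", ]), c(0, 0, 0))
  expect_equal(unname(qm2["KR preferring korean", ]), c(1, 0, 0.5))
})

test_that("preference correlation matrix is symmetric with unit diagonal", {
  set.seed(51)
  r <- simulate_responses(n_per_group = c(UK = 40, CN = 40, KR = 40),
                          seed = 51)
  qm <- question_preference_matrix(r)
  pc <- preference_correlation_matrix(qm)
  expect_equal(dim(pc$r), c(12, 12))
  expect_true(isSymmetric(pc$r))
  expect_equal(unname(diag(pc$r)), rep(1, 12))
  # planted anti-phase vectors correlate at exactly -1
  v <- rbind(a = c(0.2, 0.8, 0.4, 0.6), b = c(0.8, 0.2, 0.6, 0.4))
  pc2 <- preference_correlation_matrix(v)
  expect_equal(pc2$r["a", "b"], -1)
  # constant vectors are flagged NA rather than erroring
  v3 <- rbind(v, c = c(0.5, 0.5, 0.5, 0.5))
  pc3 <- preference_correlation_matrix(v3)
  expect_true(is.na(pc3$r["a", "c"]))
})
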