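test_that("probability of detection and precision rate formulas", {
  expect_equal(round_half_up(probability_of_detection(13, 19)), 68)
  expect_equal(probability_of_detection(20, 20), 100)
  expect_equal(probability_of_detection(0, 10), 0)
  expect_error(probability_of_detection(1, 0), "k_obs")
  expect_error(probability_of_detection(5, 4), "k_detected")

  expect_equal(precision_rate(13, 19, 0), probability_of_detection(13, 19))
  expect_equal(round_half_up(precision_rate(13, 19, 8)), 48)
  expect_equal(precision_rate(0, 10, 5), 0)
  expect_error(precision_rate(0, 0, 0), "positive")
})

test_that("precision rate never exceeds probability of detection", {
  set.seed(8)
  k_obs <- sample(5:30, 50, TRUE)
  k_det <- vapply(k_obs, function(k) sample(0:k, 1), integer(1))
  k_false <- rpois(50, 4)
  expect_true(all(precision_rate(k_det, k_obs, k_false) <=
                    probability_of_detection(k_det, k_obs)))
})

test_that("survey RMSE and MAE reproduce the seven-survey reference values", {
  obs <- c(20, 15, 18, 19, 9, 11, 6)      # North 3-6, South 3-5
  auto <- c(20, 14, 17, 15, 7, 9, 6)      # diffs 0,1,1,4,2,2,0
  man <- c(11, 10, 13, 12, 5, 6, 3)       # diffs 9,5,5,7,4,5,3
  expect_equal(survey_rmse(auto, obs), sqrt(26 / 7))
  expect_equal(round(survey_rmse(auto, obs), 4), 1.9272)
  expect_equal(round(survey_rmse(man, obs), 4), 5.7321)
  expect_equal(survey_mae(auto, obs), 10 / 7)
  expect_equal(round(survey_mae(auto, obs), 4), 1.4286)
  expect_equal(round(survey_mae(man, obs), 4), 5.4286)
  expect_equal(survey_rmse(obs, obs), 0)
  expect_equal(survey_mae(obs, obs), 0)
  expect_error(survey_rmse(numeric(), numeric()), "empty")
})

test_that("RMSE dominates MAE on random series", {
  set.seed(15)
  for (rep in 1:30) {
    n <- sample(1:10, 1)
    obs <- sample(0:30, n, TRUE)
    det <- pmax(obs - rpois(n, 3), 0)
    expect_gte(survey_rmse(det, obs), survey_mae(det, obs))
  }
})

test_that("pooled detection probability reproduces the published pools", {
  expect_equal(round_half_up(pooled_probability_of_detection(
    c(14, 17, 15, 7, 9, 6), c(15, 18, 19, 9, 11, 6))), 87)
  expect_equal(round_half_up(pooled_probability_of_detection(
    c(13, 15, 20, 5, 11), c(19, 20, 20, 5, 11))), 85)
  expect_equal(pooled_probability_of_detection(7, 9),
               probability_of_detection(7, 9))
  expect_error(pooled_probability_of_detection(numeric(), numeric()),
               "surveys")
})

test_that("false-positive composition percentages", {
  comp <- fp_composition(c(kangaroo = 21, car = 9, human = 3, other = 40))
  expect_equal(comp, c(kangaroo = 29, car = 12, human = 4, other = 55))
  expect_equal(unname(fp_composition(c(a = 7))), 100)
  expect_equal(unname(fp_composition(c(a = 2, b = 2, c = 2, d = 2))),
               rep(25, 4))
  expect_error(fp_composition(c(a = 0, b = 0)), "no false positives")
})

test_that("the survey report reproduces every bundled percentage", {
  pc <- petrie_survey_counts()
  long <- rbind(
    data.frame(survey_id = pc$survey_id, method = "automated",
               k_obs = pc$k_obs, k_detected = pc$k_auto),
    data.frame(survey_id = pc$survey_id, method = "manual",
               k_obs = pc$k_obs, k_detected = pc$k_manual))
  rep_all <- survey_report(long)
  get_pd <- function(m, s)
    rep_all$pd_pct[rep_all$method == m & rep_all$survey_id == s]
  auto_pd <- vapply(pc$survey_id, function(s) get_pd("automated", s),
                    numeric(1))
  expect_equal(unname(auto_pd),
               c(68, 75, 100, 93, 94, 79, 100, 100, 78, 82, 100))
  man_pd <- vapply(pc$survey_id, function(s) get_pd("manual", s),
                   numeric(1))
  expect_equal(unname(man_pd),
               c(47, 55, 55, 67, 72, 63, 40, 55, 56, 55, 50))

  ## pooled per role
  for (role in c("training", "testing")) {
    sub <- pc[pc$role == role, ]
    pooled_auto <- round_half_up(pooled_probability_of_detection(
      sub$k_auto, sub$k_obs))
    pooled_man <- round_half_up(pooled_probability_of_detection(
      sub$k_manual, sub$k_obs))
    if (role == "testing") {
      expect_equal(pooled_auto, 87); expect_equal(pooled_man, 63)
    } else {
      expect_equal(pooled_auto, 85); expect_equal(pooled_man, 52)
    }
  }

  ## report internal consistency: percent columns recomputable from counts
  body <- rep_all[rep_all$survey_id != "(pooled)", ]
  expect_equal(body$pd_pct,
               round_half_up(100 * body$k_detected / body$k_obs))
  ## empty input: header-only table
  expect_equal(nrow(survey_report(long[0, ])), 0)
})

test_that("report with known false counts reproduces the precision column", {
  ## North 1 automated: 13/19 with 8 unmatched signatures -> PR 48%
  rep1 <- survey_report(data.frame(survey_id = "North 1",
                                   method = "automated", k_obs = 19,
                                   k_detected = 13, k_false = 8))
  expect_equal(rep1$pr_pct[rep1$survey_id == "North 1"], 48)
})
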