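test_that("effort summaries add up and percentages re-derive from row integers", {
  set.seed(41)
  ev <- data.frame(
    trap_id = sprintf("T%02d", sample(1:20, 300, replace = TRUE)),
    trap_type = sample(c("CO2", "BG"), 300, replace = TRUE, prob = c(0.9, 0.1)),
    collection_date = as.Date("2014-03-01") + sample(0:1000, 300, replace = TRUE),
    female_count = rpois(300, 0.8), male_count = rpois(300, 0.4))
  es <- summarize_effort(ev)
  grp <- es[es$year != "Totals", ]
  tot <- es[es$year == "Totals", ]
  expect_equal(tot$n_surveys, sum(grp$n_surveys))
  expect_equal(tot$n_mosquitoes, sum(grp$n_mosquitoes))
  expect_equal(tot$n_females, sum(grp$n_females))
  expect_equal(tot$n_nonzero, sum(grp$n_nonzero))
  expect_true(all(es$n_nonzero <= es$n_surveys))
  expect_true(all(es$n_females <= es$n_mosquitoes))
  for (r in seq_len(nrow(es)))
    if (es$n_mosquitoes[r] > 0)
      expect_equal(es$pct_female[r],
                   round(100 * es$n_females[r] / es$n_mosquitoes[r] +
                           1e-12, 1))
  expect_equal(attr(es, "n_female_positive"), sum(ev$female_count >= 1))

  # a group with no mosquitoes reports NA percentages, not NaN
  empty <- data.frame(year = "2019", trap_type = "CO2", n_traps = 2,
                      n_surveys = 0, n_nonzero = 0, n_mosquitoes = 0,
                      n_females = 0)
  et <- effort_totals(empty)
  expect_true(is.na(et$pct_female[1]))
  expect_true(is.na(et$pct_nonzero[1]))
})

test_that("monthly activity pools calendar months across years", {
  ev <- data.frame(trap_id = "A",
                   collection_date = as.Date(c("2014-07-04", "2014-07-11",
                                               "2015-07-20")),
                   female_count = c(2L, 0L, 9L))
  ma <- monthly_activity(ev)
  expect_equal(ma$nonzero$Jul, c(2L, 9L))
  expect_equal(ma$n_zero[7], 1L)
  expect_true(all(lengths(ma$nonzero[-7]) == 0))

  ev2 <- data.frame(trap_id = "A",
                    collection_date = as.Date(c("2014-12-05", "2015-12-10",
                                                "2015-03-01")),
                    female_count = c(3L, 10L, 0L))
  ma2 <- monthly_activity(ev2)
  expect_equal(ma2$nonzero$Dec, c(3L, 10L))   # Decembers pool across years
  expect_equal(ma2$nonzero$Mar, integer(0))
  expect_equal(ma2$n_zero[3], 1L)
})

test_that("a constructed plateau with a jump at 0.03 yields threshold 0.02", {
  lm <- data.frame(
    trap_id = sprintf("T%03d", 1:400),
    collection_date = as.Date("2015-01-01") + 1:400,
    female_count = c(rep(c(175L, 60L, 0L, 175L), 25),     # cum20 <= 0.02
                     rep(400L, 300)),                     # above the break
    cum20 = c(runif(100, 0.0005, 0.02), runif(300, 0.0201, 0.4)))
  th <- find_low_precip_threshold(lm)
  expect_equal(th$threshold, 0.02)
  expect_equal(th$max_count_below, 175)
  expect_equal(th$pct_events_below, 100 * mean(lm$cum20 <= 0.02))
  expect_equal(th$pct_females_below,
               100 * sum(lm$female_count[lm$cum20 <= 0.02]) /
                 sum(lm$female_count))
})

test_that("identical counts everywhere plateau to the last grid value", {
  lm <- data.frame(female_count = rep(5L, 200), cum20 = runif(200, 0, 0.5))
  th <- find_low_precip_threshold(lm)
  expect_equal(th$threshold, 0.50)
  expect_equal(th$pct_events_below, 100)
})

test_that("the threshold search is order-invariant and its maximum is monotone", {
  lm <- gen_threshold_data(seed = 44)
  th <- find_low_precip_threshold(lm)
  perm <- with_seed_test(2, sample(nrow(lm)))
  th_perm <- find_low_precip_threshold(lm[perm, ])
  expect_equal(th_perm$threshold, th$threshold)
  expect_equal(th_perm$pct_females_below, th$pct_females_below)

  grid <- seq(0.01, 0.5, by = 0.01)
  M <- vapply(grid, function(t) {
    b <- lm$cum20 <= t
    if (!any(b)) NA_real_ else max(lm$female_count[b])
  }, numeric(1))
  expect_true(all(diff(M[!is.na(M)]) >= 0))
  expect_error(find_low_precip_threshold(lm[lm$cum20 > 0.3, ]),
               "smallest candidate")
})

test_that("the anthropogenic fraction is the female share below threshold", {
  lm <- data.frame(female_count = c(10L, 30L, 60L),
                   cum20 = c(0.01, 0.02, 0.30))
  expect_equal(anthropogenic_fraction(lm, 0.5), 100)
  expect_equal(anthropogenic_fraction(lm, 0.001), 0)
  expect_equal(anthropogenic_fraction(lm, 0.02), 40)
  expect_error(anthropogenic_fraction(
    data.frame(female_count = 0L, cum20 = 0.1), 0.2), "no females")
})
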