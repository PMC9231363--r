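fit_for_selection <- function() {
  sim <- tiny_planted_dataset()
  rg <- region_map_chunks(sim$data$channel_names, 4)
  list(fit = em_fit(sim$data, rg, fit_config(tau = 0.1, center = FALSE)),
       sim = sim)
}

test_that("automatic selection applies the gamma threshold and carries weights", {
  fs <- fit_for_selection()
  sel <- select_auto(fs$fit)
  expect_setequal(sel$selected, fs$sim$support)
  # weights vanish off the selected blocks and agree with the posterior on them
  st <- fs$fit$structure
  off_cols <- setdiff(seq_len(st$n_features),
                      unlist(lapply(sel$selected, function(b) (b - 1) * 4 + 1:4)))
  expect_true(all(sel$weights[off_cols] == 0))
  expect_true(any(sel$weights != 0))
  # importance is the per-block sum of absolute weights
  expect_equal(sel$importance[sel$selected[1]],
               sum(abs(fs$fit$mu[(sel$selected[1] - 1) * 4 + 1:4])))
  # a threshold above every gamma leaves nothing -> informative error
  expect_error(select_auto(fs$fit, tau = 1e9), "lower")
})

test_that("manual threshold rule on a synthetic final state", {
  fs <- fit_for_selection()
  fit <- fs$fit
  # raise the threshold until only the strongest survive
  strongest <- which.max(fit$gamma)
  sel <- select_auto(fit, tau = max(fit$gamma) * 0.999)
  expect_equal(sel$selected, strongest)
  # a threshold below every active gamma keeps all active channels
  sel_all <- select_auto(fit, tau = min(fit$gamma[fit$active]) * 0.5)
  expect_setequal(sel_all$selected, which(fit$active))
})

test_that("channel importance sums absolute weights blockwise", {
  st <- block_structure(2, 3)
  w <- c(1, -1, 2, 0, 0, 0)
  expect_equal(channel_importance(w, st), c(4, 0))
  set.seed(6)
  w2 <- rnorm(6)
  expect_equal(channel_importance(w2, st),
               c(sum(abs(w2[1:3])), sum(abs(w2[4:6]))))
})

test_that("fixed-M selection ranks by importance and backfills from removals", {
  fs <- fit_for_selection()
  sel <- select_auto(fs$fit)
  # ranking: with M = 2, the two most important selected channels, descending
  top2 <- select_top_m(sel, 2)
  ord <- sel$selected[order(-sel$importance[sel$selected], sel$selected)]
  expect_equal(top2, ord[1:2])
  # M equal to the selection size returns exactly the auto selection
  expect_setequal(select_top_m(sel, length(sel$selected)), sel$selected)
  # backfill: most recently deleted first
  need <- length(sel$selected) + 2
  got <- select_top_m(sel, need)
  expect_equal(got, c(sel$selected, rev(sel$removal_order)[1:2]))
  # M = N_c returns every channel
  n_c <- length(sel$channel_names)
  expect_setequal(select_top_m(sel, n_c), seq_len(n_c))
  expect_error(select_top_m(sel, 0), "must be in")
  expect_error(select_top_m(sel, n_c + 1), "must be in")
})

test_that("synthetic backfill order follows the documented rule", {
  sel <- structure(
    list(selected = c(3L, 5L), importance = c(0, 0, 3, 0, 1, 0),
         weights = numeric(12), removal_order = c(2L, 6L, 1L, 4L),
         channel_names = paste0("C", 1:6), tau = 0.1,
         structure = block_structure(6, 2)),
    class = "channel_selection")
  # latest deletions first: 4 then 1
  expect_equal(select_top_m(sel, 4), c(3L, 5L, 4L, 1L))
  expect_equal(select_top_m(sel, 2), c(3L, 5L))   # importance 3 > 1
})

test_that("mean-minus-half-sd thresholding matches its arithmetic", {
  expect_setequal(baseline_auto_threshold(rep(5, 7)), 1:7)  # sd 0: all pass
  imp <- c(10, 10, 0, 0)
  expect_setequal(baseline_auto_threshold(imp), c(1, 2))
  set.seed(14)
  v <- runif(20)
  expect_setequal(baseline_auto_threshold(v),
                  which(v > mean(v) - 0.5 * sd(v)))
})

test_that("selection tables are tidy and exportable", {
  fs <- fit_for_selection()
  sel <- select_auto(fs$fit)
  td <- tidy(sel)
  expect_equal(nrow(td), length(sel$channel_names))
  expect_setequal(td$channel_index[td$selected], sel$selected)
  expect_false(any(duplicated(td$channel)))
  f <- withr::local_tempfile(fileext = ".csv")
  nm <- withr::local_tempfile(fileext = ".txt")
  write_selection(sel, f, nm)
  expect_equal(readLines(nm), sel$channel_names[sel$selected])
  expect_equal(nrow(utils::read.csv(f)), nrow(td))
})
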