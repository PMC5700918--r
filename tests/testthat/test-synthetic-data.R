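test_that("default factorial design yields one conserved record per cell", {
  tab <- generate_bioassay(bioassay_design(), seed = 1)
  expect_equal(nrow(tab), 4 * 2 * 2 * 4)
  counts <- tab[c("on_fed", "on_notfed", "off_fed", "off_notfed",
                  "unrecovered")]
  expect_true(all(rowSums(counts) == tab$released))
  expect_true(all(as.matrix(counts) >= 0))
  # every block x strain x variety x interval cell appears exactly once
  key <- with(tab, paste(block, strain, variety, interval_h))
  expect_equal(anyDuplicated(key), 0L)
})

test_that("degenerate probabilities put every larva in on_fed", {
  tab <- generate_bioassay(bioassay_design(), all_on_fed_params(), seed = 1)
  expect_true(all(tab$on_fed == 20))
  expect_true(all(tab$on_notfed == 0 & tab$off_fed == 0 &
                  tab$off_notfed == 0 & tab$unrecovered == 0))
})

test_that("identical seeds give identical tables, different seeds differ", {
  a <- generate_bioassay(bioassay_design(), seed = 42)
  b <- generate_bioassay(bioassay_design(), seed = 42)
  c <- generate_bioassay(bioassay_design(), seed = 43)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, c)))
})

test_that("invalid designs and parameters are rejected", {
  expect_error(bioassay_design(n_blocks = 0), "positive")
  expect_error(bioassay_design(strains = character(0)), "empty")
  expect_error(bioassay_design(intervals_h = c(6, 6, 12)), "unique")
  expect_error(bioassay_design(intervals_h = c(12, 6)), "increasing")
  expect_error(bioassay_params(on_plant_prob = const_mat(1.2, 6)),
               "\\[0, 1\\]")
  expect_error(generate_bioassay(
    bioassay_design(strains = "XX"), bioassay_params()), "XX")
})

test_that("empirical survival is calibrated to the logistic model", {
  # 100,000 larvae in one design cell per time point; empirical survival
  # must sit within 3 Monte-Carlo standard errors of the model
  design <- bioassay_design(n_blocks = 1000, strains = "SS",
                            varieties = "NONBT", larvae_per_plant = 100)
  tab <- generate_bioassay(design, seed = 7)
  for (t_h in design$intervals_h) {
    sub <- tab[tab$interval_h == t_h, ]
    n <- sum(sub$released)
    p_hat <- 1 - sum(sub$unrecovered) / n
    p <- plogis(2.7690 - 0.1470 * t_h)
    expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("blocks are generated independently", {
  # counts in one block do not repeat verbatim across blocks
  tab <- generate_bioassay(bioassay_design(n_blocks = 6, strains = "SS",
                                           varieties = "NONBT"), seed = 5)
  per_block <- split(tab$on_fed, tab$block)
  expect_gt(length(unique(vapply(per_block, paste, character(1),
                                 collapse = ","))), 1)
})

test_that("zero-dispersion tracks equal their group means exactly", {
  tr <- generate_tracks(5, dispersion = 0, seed = 1)
  means <- default_track_means()
  for (g in seq_len(nrow(means))) {
    sub <- tr[tr$strain == means$strain[g] & tr$variety == means$variety[g], ]
    expect_equal(sub$distance_cm, rep(means$distance_cm[g], 5))
    expect_equal(sub$velocity_cm_s, rep(means$velocity_cm_s[g], 5))
    expect_equal(sub$mobility_s, rep(means$mobility_s[g], 5))
  }
})

test_that("default distance means encode the 3:1 Bt vs non-Bt contrast", {
  tr <- generate_tracks(1e4, seed = 2)
  m_bt <- mean(tr$distance_cm[tr$strain == "RR" & tr$variety == "BT_WS"])
  m_nb <- mean(tr$distance_cm[tr$strain == "RR" & tr$variety == "NONBT"])
  expect_gt(m_bt / m_nb, 2.7)
  expect_lt(m_bt / m_nb, 3.3)
})

test_that("track table shape and validation", {
  tr <- generate_tracks(4, seed = 1)
  expect_equal(nrow(tr), 16) # 4 larvae x 2 strains x 2 varieties
  expect_true(all(tr$distance_cm > 0 & tr$velocity_cm_s > 0 &
                  tr$mobility_s > 0))
  bad <- default_track_means()
  bad$distance_cm[1] <- 0
  expect_error(generate_tracks(4, group_means = bad), "positive")
  expect_error(generate_tracks(0), ">= 1")
})
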