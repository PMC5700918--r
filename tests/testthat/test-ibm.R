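# small helper grids
empty_grid <- function(n = 10) matrix(0L, n, n)
one_larva <- function(n = 10, at = c(5, 5)) {
  g <- empty_grid(n)
  g[at[1], at[2]] <- 1L
  g
}

test_that("frozen dynamics leave the grids unchanged", {
  land <- build_landscape(10, 10, "BT", 0)
  g <- one_larva()
  set.seed(1)
  expect_identical(larval_dispersal_step(g, land, 0, 0), g)
  rates0 <- transition_rates(0, 0, 0, 0)
  st <- transition_step(g, empty_grid(), rates0)
  expect_identical(st$larvae, g)
  expect_identical(st$adults, empty_grid())
})

test_that("a full grid cannot move (single-occupancy exclusion)", {
  land <- build_landscape(6, 6, "BT", 0)
  full <- matrix(1L, 6, 6)
  set.seed(2)
  expect_identical(larval_dispersal_step(full, land), full)
})

test_that("one dispersal step stays within the crop's Chebyshev radius", {
  for (seed in 1:25) {
    set.seed(seed)
    land_bt <- build_landscape(15, 15, "BT", 0)
    g <- larval_dispersal_step(one_larva(15, c(8, 8)), land_bt)
    pos <- which(g == 1L, arr.ind = TRUE)
    expect_equal(sum(g), 1)
    expect_lte(max(abs(pos - 8)), 3)
    land_nb <- build_landscape(15, 15, "NONBT", 0)
    g2 <- larval_dispersal_step(one_larva(15, c(8, 8)), land_nb)
    pos2 <- which(g2 == 1L, arr.ind = TRUE)
    expect_lte(max(abs(pos2 - 8)), 1)
  }
})

test_that("adult moves respect radius and carrying capacity", {
  # saturated destination ring: no adult can move
  A <- matrix(10L, 5, 5)
  set.seed(3)
  expect_identical(adult_dispersal_step(A, radius = 2), A)
  # single adult stays within Chebyshev radius
  for (seed in 1:10) {
    set.seed(seed)
    A1 <- matrix(0L, 80, 80)
    A1[40, 40] <- 1L
    moved <- adult_dispersal_step(A1, radius = 35)
    pos <- which(moved == 1L, arr.ind = TRUE)
    expect_equal(sum(moved), 1)
    expect_lte(max(abs(pos - 40)), 35)
  }
})

test_that("transition events follow their stated semantics", {
  g <- one_larva()
  # certain immature mortality empties the larval grid
  set.seed(4)
  st <- transition_step(g, empty_grid(), transition_rates(1, 0, 0, 0))
  expect_equal(sum(st$larvae), 0)
  expect_equal(sum(st$adults), 0)
  # certain metamorphosis converts every larva into one female
  block <- empty_grid()
  block[3:6, 3:6] <- 1L
  set.seed(5)
  st2 <- transition_step(block, empty_grid(), transition_rates(0, 1, 0, 0))
  expect_equal(sum(st2$larvae), 0)
  expect_equal(sum(st2$adults), sum(block))
  expect_identical(which(st2$adults == 1L), which(block == 1L))
  # certain oviposition fills exactly the empty slots under females
  A <- empty_grid()
  A[2, 2] <- 3L
  A[7, 7] <- 1L
  set.seed(6)
  st3 <- transition_step(one_larva(10, c(2, 2)), A,
                         transition_rates(0, 0, 0, 1))
  expect_equal(st3$larvae[2, 2], 1L) # already occupied, stays single
  expect_equal(st3$larvae[7, 7], 1L)
  expect_equal(sum(st3$larvae), 2)
  # certain adult mortality clears the adult grid
  set.seed(7)
  st4 <- transition_step(empty_grid(), A, transition_rates(0, 0, 1, 0))
  expect_equal(sum(st4$adults), 0)
})

test_that("metamorphosis respects the adult carrying capacity", {
  g <- one_larva(5, c(3, 3))
  A <- matrix(0L, 5, 5)
  A[3, 3] <- 10L
  set.seed(8)
  st <- transition_step(g, A, transition_rates(0, 1, 0, 0),
                        carrying_capacity = 10)
  expect_equal(st$adults[3, 3], 10L) # female lost at capacity
  expect_equal(st$larvae[3, 3], 0L)
})

test_that("dispersal conserves counts and occupancy bounds over a run", {
  set.seed(9)
  land <- build_landscape(20, 20, "BT", 0.2)
  g <- empty_grid(20)
  g[8:13, 8:13] <- 1L
  A <- empty_grid(20)
  A[10, 10] <- 7L
  n_l <- sum(g)
  n_a <- sum(A)
  for (s in 1:30) {
    g <- larval_dispersal_step(g, land)
    A <- adult_dispersal_step(A, radius = 5)
    expect_equal(sum(g), n_l)
    expect_equal(sum(A), n_a)
    expect_true(all(g %in% c(0L, 1L)))
    expect_true(all(A >= 0L & A <= 10L))
  }
})

test_that("invalid grids and rates are rejected", {
  land <- build_landscape(5, 5, "BT", 0)
  bad <- matrix(2L, 5, 5)
  expect_error(larval_dispersal_step(bad, land), "0/1")
  expect_error(adult_dispersal_step(matrix(11L, 5, 5)), "carrying_capacity")
  expect_error(transition_rates(-0.1, 0, 0, 0), "\\[0, 1\\]")
  expect_error(transition_rates(oviposition = 1.7), "\\[0, 1\\]")
})

test_that("distance endpoint matches geometry and the brute-force oracle", {
  expect_equal(mean_distance_to_centre(one_larva()), 0)
  two <- empty_grid()
  two[3, 1] <- 1L
  two[3, 3] <- 1L # points (0,0) and (0,2) one axis apart by 2
  expect_equal(mean_distance_to_centre(two), 1)
  corners <- empty_grid(2)
  corners[] <- 1L # unit square corners
  expect_equal(mean_distance_to_centre(corners), sqrt(2) / 2)
  expect_error(mean_distance_to_centre(empty_grid()), "no larvae")
  for (seed in 1:20) {
    set.seed(seed)
    g <- matrix(rbinom(400, 1, 0.3), 20, 20)
    if (sum(g) == 0) next
    expect_equal(mean_distance_to_centre(g), mean_distance_oracle(g),
                 tolerance = 1e-10)
  }
})

test_that("larval density is occupied cells over total cells", {
  expect_equal(larval_density(empty_grid()), 0)
  expect_equal(larval_density(matrix(1L, 4, 4)), 1)
  g <- empty_grid(10)
  g[1, 1:10] <- 1L
  expect_equal(larval_density(g), 0.10)
})

test_that("replicates are deterministic under a seed", {
  cf <- scenario_config("a1", "BT", 0.1, width = 25, height = 25,
                        steps = 20, replicates = 2, init_block = 8)
  r1 <- run_replicate(cf, seed = 123)
  r2 <- run_replicate(cf, seed = 123)
  expect_identical(r1, r2)
  r3 <- run_replicate(cf, seed = 124)
  expect_false(identical(r1$mean_distance, r3$mean_distance))
})

test_that("steps = 0 returns the endpoints of the initial configuration", {
  cf <- scenario_config("a1", "BT", 0, width = 30, height = 30,
                        steps = 0, init_block = 10)
  r <- run_replicate(cf, seed = 1)
  # 10x10 centred block: density 100/900, distance of the block itself
  expect_equal(r$larval_density, 100 / 900)
  expect_equal(r$final_larvae, 100)
  block <- matrix(0L, 30, 30)
  block[11:20, 11:20] <- 1L
  expect_equal(r$mean_distance, mean_distance_to_centre(block))
})

test_that("frozen-dynamics replicates keep initial endpoints at any steps", {
  cf <- scenario_config("a1", "BT", 0, width = 30, height = 30,
                        radius_bt = 0, radius_nonbt = 0, adult_radius = 0,
                        steps = 40, init_block = 10,
                        rates = transition_rates(0, 0, 0, 0))
  r <- run_replicate(cf, seed = 5)
  cf0 <- scenario_config("a1", "BT", 0, width = 30, height = 30,
                         steps = 0, init_block = 10)
  r0 <- run_replicate(cf0, seed = 5)
  expect_equal(r$mean_distance, r0$mean_distance)
  expect_equal(r$larval_density, r0$larval_density)
})

test_that("extinct replicates are flagged, not erroring", {
  cf <- scenario_config("a1", "BT", 0, width = 20, height = 20,
                        steps = 3, init_block = 5,
                        rates = transition_rates(1, 0, 1, 0))
  r <- run_replicate(cf, seed = 1)
  expect_true(is.na(r$mean_distance))
  expect_equal(r$larval_density, 0)
  expect_equal(r$final_larvae, 0)
})

test_that("expected spread grows with the larval radius", {
  # movement-only regime isolates the kernel: radius 3 vs radius 1
  dist_for <- function(r_bt, seeds) {
    cf <- scenario_config("x", "BT", 0, width = 60, height = 60,
                          radius_bt = r_bt, adult_radius = 0,
                          steps = 25, init_block = 10,
                          rates = transition_rates(0, 0, 0, 0))
    vapply(seeds, function(s) run_replicate(cf, seed = s)$mean_distance,
           numeric(1))
  }
  d3 <- dist_for(3, 1:50)
  d1 <- dist_for(1, 1:50)
  tt <- t.test(d3, d1, alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})

test_that("a smoke battery has the right shape and comparison tables", {
  battery <- default_battery(seed = 1, width = 25, height = 25, steps = 5,
                             replicates = 2, init_block = 8)
  expect_named(battery, c("a1", "a2", "a3", "b1", "b2", "b3"))
  res <- run_battery(battery, seed = 1)
  expect_equal(nrow(res$results), 12)
  expect_equal(sort(unique(res$results$scenario)), names(battery))
  expect_s3_class(res$tukey$mean_distance, "tukey_cmp")
  expect_equal(nrow(res$tukey$mean_distance$letters), 6)
  # determinism of the whole battery under the master seed
  res2 <- run_battery(battery, seed = 1)
  expect_identical(res$results, res2$results)
})
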