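# constructed realized axes: plan axis tilted by a known angle about a
# perpendicular through a mid-shaft pivot
tilted_axes <- function(plans, tilts) {
  out <- list()
  for (nm in names(plans)) {
    pl <- plans[[nm]]
    perp <- sacronav:::perpendicular_unit(pl$direction,
                                          salt = match(nm, names(plans)))
    R <- rotation_about_axis(perp, tilts[[nm]])
    mid <- pl$entry + 15 * pl$direction
    d2 <- as.numeric(R %*% pl$direction)
    out[[nm]] <- line3d(mid - 15 * d2, d2)
  }
  out
}

test_that("drilling along the plan reports near-zero angles and grade A", {
  ph <- default_phantom()
  plans <- ph$truth$plans
  realized <- lapply(plans, function(pl) line3d(pl$entry, pl$direction))
  pd <- simulate_postdrill_volume(ph$truth, realized, rigid_transform())
  rep <- evaluate_drilling(plans, pd, ph$truth$true_surfaces$bone)
  expect_true(all(rep$per_trajectory$angle_deg < 0.5))
  expect_true(all(rep$per_trajectory$grade == "A"))
})

test_that("a constructed tilt is measured back within half a degree", {
  ph <- default_phantom()
  plans <- ph$truth$plans
  realized <- tilted_axes(plans, c(S1 = 4.42, ALA = 2.4))
  pose <- rigid_transform(rotation_about_axis(c(1, 2, 0.5), 6), c(8, -5, 3))
  pd <- simulate_postdrill_volume(ph$truth, realized, pose)
  rep <- cached("eval_tilted", evaluate_drilling(
    plans, pd, ph$truth$true_surfaces$bone))
  tab <- rep$per_trajectory
  expect_lt(abs(tab$angle_deg[tab$trajectory == "S1"] - 4.42), 0.5)
  expect_lt(abs(tab$angle_deg[tab$trajectory == "ALA"] - 2.4), 0.5)
  expect_true(all(tab$grade == "A"))
})

test_that("the measurement is invariant to rigid motion of the scene", {
  ph <- default_phantom()
  plans <- ph$truth$plans
  realized <- tilted_axes(plans, c(S1 = 4.42, ALA = 2.4))
  rep1 <- cached("eval_tilted", evaluate_drilling(
    plans,
    simulate_postdrill_volume(ph$truth, realized,
                              rigid_transform(
                                rotation_about_axis(c(1, 2, 0.5), 6),
                                c(8, -5, 3))),
    ph$truth$true_surfaces$bone))
  pose2 <- rigid_transform(rotation_about_axis(c(-1, 0.3, 1), 11),
                           c(-6, 9, -4))
  rep2 <- evaluate_drilling(plans,
                            simulate_postdrill_volume(ph$truth, realized,
                                                      pose2),
                            ph$truth$true_surfaces$bone)
  d <- abs(rep1$per_trajectory$angle_deg - rep2$per_trajectory$angle_deg)
  expect_true(all(d < 0.2))
})

test_that("a bit-count mismatch against the plan set errors", {
  ph <- default_phantom()
  plans <- ph$truth$plans
  one <- list(S1 = line3d(plans$S1$entry, plans$S1$direction))
  pd <- simulate_postdrill_volume(ph$truth, one, rigid_transform())
  expect_error(evaluate_drilling(plans, pd, ph$truth$true_surfaces$bone),
               "1 drill bits but 2")
})
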