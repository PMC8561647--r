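# small three-shell head: fast factorization, deliberately coarse (flat)
# observation sampling unless focused
small_head <- function(r_skin = 92) {
  head_model(list(skin = icosphere(r_skin, 2L), GM = icosphere(80, 2L),
                  WM = icosphere(77.5, 2L)),
             c(skin = 0.465, GM = 0.276, WM = 0.126))
}
small_case <- function() {
  h <- small_head()
  sys <- assemble_system(h)
  obs <- build_observation_surface(head_shell(h, "GM"), head_shell(h, "WM"))
  tgt <- head_shell(h, "GM")$vertices[which.max(head_shell(h, "GM")$vertices[, 3]), ]
  cl <- make_loop_coil(radius = 20)
  pose <- coil_pose(center = c(0, 0, 92 + 16))
  list(h = h, sys = sys, obs = obs, tgt = tgt, cl = cl, pose = pose)
}

test_that("infeasible poses carry the +Inf sentinel and skip the solve", {
  cs <- small_case()
  before <- cs$sys$counters$solves
  low <- coil_pose(center = c(0, 0, 92 + 5))
  ev <- evaluate_pose(cs$sys, cs$cl, low, cs$obs, cs$tgt)
  expect_false(ev$feasible)
  expect_identical(ev$aad, Inf)
  expect_lt(ev$clearance, 10)
  expect_equal(cs$sys$counters$solves, before)   # no forward solve performed
})

test_that("pose evaluation is deterministic and caches correctly", {
  cs <- small_case()
  e1 <- evaluate_pose(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt)
  e2 <- evaluate_pose(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt)
  expect_identical(e1$aad, e2$aad)
  # cached path returns the same scalar without a new solve
  e3 <- evaluate_pose(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt, use_cache = TRUE)
  n <- cs$sys$counters$solves
  e4 <- evaluate_pose(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt, use_cache = TRUE)
  expect_identical(cs$sys$counters$solves, n)
  expect_identical(e3$aad, e4$aad)
  expect_identical(e3$aad, e1$aad)
})

test_that("a pose can be evaluated across head models (segmentation swap)", {
  csA <- small_case()
  hB <- head_model(list(skin = icosphere(92, 2L), GM = icosphere(79, 2L),
                        WM = icosphere(76.5, 2L)),
                   c(skin = 0.465, GM = 0.276, WM = 0.126))
  sysB <- assemble_system(hB)
  obsB <- build_observation_surface(head_shell(hB, "GM"), head_shell(hB, "WM"))
  evA <- evaluate_pose(csA$sys, csA$cl, csA$pose, csA$obs, csA$tgt)
  evB <- evaluate_pose(sysB, csA$cl, csA$pose, obsB, csA$tgt)
  expect_true(is.finite(evB$aad))
  expect_false(isTRUE(all.equal(evA$aad, evB$aad)))
})

test_that("descent is monotone and its output is a grid fixed point", {
  cs <- small_case()
  tr <- descend(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt)
  expect_true(all(diff(tr$iterations$aad) <= 1e-12))
  expect_true(tr$saturated)
  # restarting from the accepted solution changes nothing: one pass, no move
  tr2 <- descend(cs$sys, cs$cl, tr$poses[[tr$accepted_index]], cs$obs, cs$tgt)
  expect_equal(tr2$passes, 1L)
  expect_equal(nrow(tr2$iterations), 1L)
  expect_error(descend(cs$sys, cs$cl, coil_pose(center = c(0, 0, 95)),
                       cs$obs, cs$tgt), "clearance")
})

test_that("defocalization averages the perturbation ratios (incl. n = 0)", {
  cs <- small_case()
  df <- defocalization(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt)
  # manual recomputation oracle, rebuilding each perturbed pose from scratch
  cfg <- search_config()
  ev0 <- evaluate_pose(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt)
  ratios <- 1
  for (var in c("x", "y", "z", "pitch", "roll", "yaw")) {
    step <- if (var %in% c("x", "y", "z")) cfg$df_step_linear else cfg$df_step_angular
    for (sgn in c(-1, 1)) {
      p <- tmsfocal:::pose_set(cs$pose, var,
                               tmsfocal:::pose_get(cs$pose, var) + sgn * step)
      evp <- evaluate_pose(cs$sys, cs$cl, p, cs$obs, cs$tgt)
      if (evp$feasible) ratios <- c(ratios, evp$aad / ev0$aad)
    }
  }
  expect_equal(df, mean(ratios), tolerance = 1e-12)
  # 12-term variant drops the unperturbed ratio
  cfg12 <- search_config(df_include_unperturbed = FALSE)
  df12 <- defocalization(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt, cfg = cfg12)
  expect_equal(df12, mean(ratios[-1]), tolerance = 1e-12)
})

test_that("stability correction accepts stable solutions unchanged", {
  cs <- small_case()
  tr <- descend(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt)
  tr2 <- stability_correct(tr, cs$sys, cs$cl, cs$obs, cs$tgt)
  expect_equal(tr2$accepted_index, length(tr$poses))
  expect_equal(length(tr2$df_history), 1L)
  expect_lt(attr(tr2, "df_final"), 1.25)
})

test_that("exhaustive search returns the grid minimum and enforces the cap", {
  cs <- small_case()
  grid <- list(x = c(-4, -2, 0, 2, 4), yaw = c(-0.1, 0, 0.1))
  ex <- exhaustive_search(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt, grid)
  # manual enumeration oracle
  best <- Inf
  for (dx in grid$x) for (dy in grid$yaw) {
    p <- coil_pose(center = cs$pose$center + c(dx, 0, 0), yaw = dy)
    ev <- evaluate_pose(cs$sys, cs$cl, p, cs$obs, cs$tgt)
    if (ev$feasible) best <- min(best, ev$aad)
  }
  expect_equal(ex$aad, best, tolerance = 1e-12)
  expect_equal(ex$n_total, 15)
  # the grid contains the center pose, so the minimum can never be worse
  ev0 <- evaluate_pose(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt)
  expect_lte(ex$aad, ev0$aad + 1e-12)
  expect_error(exhaustive_search(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt,
                                 list(x = seq(-10, 10, 0.1)), max_poses = 100),
               "cap")
})

test_that("run_ip where descent cannot improve reports zero change", {
  # ultra-coarse observation sampling: the suprathreshold set cannot change
  # membership at the probe scale, so the initial pose is already optimal
  h <- head_model(list(skin = icosphere(92, 2L), GM = icosphere(80, 1L),
                       WM = icosphere(77.5, 1L)),
                  c(skin = 0.465, GM = 0.276, WM = 0.126))
  sys <- assemble_system(h)
  obs <- build_observation_surface(head_shell(h, "GM"), head_shell(h, "WM"))
  tgt <- head_shell(h, "GM")$vertices[which.max(head_shell(h, "GM")$vertices[, 3]), ]
  ts <- structure(list(target = tgt,
                       neighbors = matrix(numeric(0), 0, 3),
                       nearest_obs_nodes = NULL), class = "target_set")
  rep <- suppressMessages(run_ip(sys, coil_preset("small"), ts, obs))
  expect_equal(rep$aad_final, rep$aad_initial, tolerance = 1e-12)
  expect_equal(rep$improvement, 0, tolerance = 1e-9)
  expect_equal(rep$field_loss, 0, tolerance = 1e-9)
  expect_true(is.na(rep$ard_initial))   # no neighbours -> ARD undefined
})

test_that("tangential mode varies yaw and scalp-tangential moves only", {
  cs <- small_case()
  cfg <- search_config(mode = "tangential3", max_passes = 2L)
  tr <- descend(cs$sys, cs$cl, cs$pose, cs$obs, cs$tgt, cfg)
  expect_true(all(tr$iterations$variable %in% c("init", "yaw", "t1", "t2")))
  expect_true(all(diff(tr$iterations$aad) <= 1e-12))
})
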