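#' Search configuration for the pose optimization
#'
#' Defaults reproduce the study settings: 2 mm / 0.1 rad descent steps,
#' 1.5 mm / 0.1 rad stability perturbations, instability limit
#' `DF >= 1.25`, and the 10 mm coil-scalp clearance constraint.
#'
#' @param step_linear,step_angular descent probe steps (mm / rad).
#' @param df_step_linear,df_step_angular stability-perturbation steps.
#' @param df_limit defocalization limit above which a solution is
#'   classified unstable.
#' @param max_passes maximum descent passes.
#' @param saturation_tol per-pass AAD decrease (mm) below which the
#'   descent is considered saturated.
#' @param min_clearance coil-scalp constraint (mm).
#' @param mode `"full6d"` or `"tangential3"` (yaw plus two
#'   scalp-tangential translations, centerline re-normalized to the skin
#'   after every move).
#' @param df_include_unperturbed include the unperturbed ratio (exactly 1)
#'   in the defocalization mean (13-term form) or not (12-term form).
#' @param revert_granularity stability reversion steps back by single
#'   accepted update (`"update"`) or by whole pass (`"pass"`).
#' @return object of class `search_config`.
#' @export
search_config <- function(step_linear = 2, step_angular = 0.1,
                          df_step_linear = 1.5, df_step_angular = 0.1,
                          df_limit = 1.25, max_passes = 20L,
                          saturation_tol = 0.05, min_clearance = 10,
                          mode = c("full6d", "tangential3"),
                          df_include_unperturbed = TRUE,
                          revert_granularity = c("update", "pass")) {
  mode <- match.arg(mode)
  revert_granularity <- match.arg(revert_granularity)
  stopifnot(step_linear > 0, step_angular > 0, df_step_linear > 0,
            df_step_angular > 0, df_limit > 1)
  structure(list(step_linear = step_linear, step_angular = step_angular,
                 df_step_linear = df_step_linear,
                 df_step_angular = df_step_angular, df_limit = df_limit,
                 max_passes = as.integer(max_passes),
                 saturation_tol = saturation_tol,
                 min_clearance = min_clearance, mode = mode,
                 df_include_unperturbed = df_include_unperturbed,
                 revert_granularity = revert_granularity),
            class = "search_config")
}

#' Evaluate one coil pose
#'
#' Checks the coil-scalp clearance first: poses closer than
#' `min_clearance` are infeasible and are excluded without a forward solve
#' (AAD carries a `+Inf` sentinel). Feasible poses get a right-hand-side
#' solve against the factorized operator and an AAD evaluation on the
#' observation surface.
#'
#' @param system a `forward_system`.
#' @param coil local-frame `coil`.
#' @param pose `coil_pose`.
#' @param obs `observation_surface`.
#' @param target 3-vector, mm.
#' @param mcfg [metric_config()].
#' @param min_clearance clearance constraint, mm.
#' @param dIdt pulse strength, A/s.
#' @param use_cache memoize the scalar result in the system's pose cache
#'   (the search paths enable this; identical poses then cost nothing).
#' @return list with `aad`, `field` (`NULL` when infeasible and absent on
#'   cache hits), `feasible`, `clearance`.
#' @export
evaluate_pose <- function(system, coil, pose, obs, target,
                          mcfg = metric_config(), min_clearance = 10,
                          dIdt = 9.4e7, use_cache = FALSE) {
  key <- NULL
  if (use_cache) {
    if (is.null(system$cache)) stop("forward system carries no cache")
    key <- paste(c(sprintf("%.9g", c(pose$center, pose$pitch, pose$roll,
                                     pose$yaw, target, mcfg$field_threshold,
                                     min_clearance, dIdt)),
                   obs$id), collapse = "|")
    hit <- system$cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  skin <- head_shell(system$head, names(system$head$shells)[1])
  clr <- coil_scalp_clearance(transform_coil(coil, pose), skin)
  if (clr < min_clearance) {
    out <- list(aad = Inf, field = NULL, feasible = FALSE, clearance = clr)
    if (use_cache) system$cache[[key]] <- out
    return(out)
  }
  charges <- solve_charges(system, coil, pose, dIdt)
  fld <- total_field(system, charges, coil, pose, obs$points)
  out <- list(aad = aad(fld, target, mcfg$field_threshold), field = fld,
              feasible = TRUE, clearance = clr)
  if (use_cache) {
    light <- out
    light$field <- NULL   # cache the scalar cost only, not the field map
    system$cache[[key]] <- light
  }
  out
}

pose_get <- function(pose, var) {
  switch(var, x = pose$center[1], y = pose$center[2], z = pose$center[3],
         pitch = pose$pitch, roll = pose$roll, yaw = pose$yaw)
}

pose_set <- function(pose, var, value) {
  switch(var,
         x = { pose$center[1] <- value; pose },
         y = { pose$center[2] <- value; pose },
         z = { pose$center[3] <- value; pose },
         pitch = { pose$pitch <- value; pose },
         roll = { pose$roll <- value; pose },
         yaw = { pose$yaw <- value; pose })
}

# tangential move: shift the centerline-skin intersection in the local
# tangent plane and rebuild the pose perpendicular to the skin there,
# keeping yaw and the standoff along the centerline
tangential_move <- function(system, coil, pose, dt1, dt2, standoff_eff) {
  skin <- head_shell(system$head, names(system$head$shells)[1])
  u <- as.numeric(pose_rotation(pose) %*% coil$normal_axis)
  hit <- ray_mesh_intersect(skin, pose$center, -u)
  p0 <- if (is.null(hit)) surface_normal_at(skin, pose$center)$closest else hit$point
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * u) * u; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  sn <- surface_normal_at(skin, p0 + dt1 * t1 + dt2 * t2)
  u2 <- sn$normal
  center <- sn$closest + standoff_eff * u2
  pose2 <- pose_from_axes(center, u2, h_des = NULL, handle_local = coil$handle_axis)
  pose2$yaw <- pose$yaw
  pose2
}

#' Sequential coordinate-descent pose search
#'
#' Per pass the variables are updated in the order yaw, pitch, roll, x, y,
#' z; each is probed at `{v - step, v, v + step}` and the minimizer adopted
#' immediately (ties keep the current value). Passes repeat until the
#' per-pass AAD decrease falls below `saturation_tol` or `max_passes` is
#' reached. In `tangential3` mode only yaw and two scalp-tangential
#' translations are varied, with the centerline re-normalized to the skin
#' after each move.
#'
#' @param system a `forward_system`.
#' @param coil local-frame `coil`.
#' @param pose0 feasible starting `coil_pose`.
#' @param obs `observation_surface`.
#' @param target 3-vector, mm.
#' @param cfg [search_config()].
#' @param mcfg [metric_config()].
#' @param dIdt pulse strength, A/s.
#' @return object of class `ip_trace`: `iterations` (data frame of
#'   accepted updates with pass, variable, pose parameters and AAD),
#'   `poses` (list of accepted poses), `accepted_index`, `df_history`,
#'   `passes`, `n_evals`.
#' @export
descend <- function(system, coil, pose0, obs, target, cfg = search_config(),
                    mcfg = metric_config(), dIdt = 9.4e7) {
  ev0 <- evaluate_pose(system, coil, pose0, obs, target, mcfg,
                       cfg$min_clearance, dIdt, use_cache = TRUE)
  if (!ev0$feasible) stop("descend: initial pose violates the clearance constraint")
  standoff_eff <- ev0$clearance
  rows <- list(); poses <- list()
  add <- function(pass, var, pose, aadv) {
    rows[[length(rows) + 1L]] <<- data.frame(
      pass = pass, variable = var, x = pose$center[1], y = pose$center[2],
      z = pose$center[3], pitch = pose$pitch, roll = pose$roll,
      yaw = pose$yaw, aad = aadv)
    poses[[length(poses) + 1L]] <<- pose
  }
  cur_pose <- pose0; cur_aad <- ev0$aad
  add(0L, "init", cur_pose, cur_aad)
  n_evals <- 1L
  passes <- 0L
  full_vars <- c("yaw", "pitch", "roll", "x", "y", "z")
  repeat {
    passes <- passes + 1L
    aad_at_pass_start <- cur_aad
    if (cfg$mode == "full6d") {
      for (var in full_vars) {
        step <- if (var %in% c("x", "y", "z")) cfg$step_linear else cfg$step_angular
        v0 <- pose_get(cur_pose, var)
        cand_poses <- list(pose_set(cur_pose, var, v0 - step),
                           pose_set(cur_pose, var, v0 + step))
        cand_aad <- vapply(cand_poses, function(p) {
          evaluate_pose(system, coil, p, obs, target, mcfg,
                        cfg$min_clearance, dIdt, use_cache = TRUE)$aad
        }, 1)
        n_evals <- n_evals + 2L
        best <- which.min(cand_aad)
        if (cand_aad[best] < cur_aad) {      # ties keep the current value
          cur_pose <- cand_poses[[best]]
          cur_aad <- cand_aad[best]
          add(passes, var, cur_pose, cur_aad)
        }
      }
    } else {
      for (var in c("yaw", "t1", "t2")) {
        if (var == "yaw") {
          v0 <- cur_pose$yaw
          cand_poses <- list(pose_set(cur_pose, "yaw", v0 - cfg$step_angular),
                             pose_set(cur_pose, "yaw", v0 + cfg$step_angular))
        } else {
          s <- cfg$step_linear
          d <- if (var == "t1") c(-s, 0, s, 0) else c(0, -s, 0, s)
          cand_poses <- list(
            tangential_move(system, coil, cur_pose, d[1], d[2], standoff_eff),
            tangential_move(system, coil, cur_pose, d[3], d[4], standoff_eff))
        }
        cand_aad <- vapply(cand_poses, function(p) {
          evaluate_pose(system, coil, p, obs, target, mcfg,
                        cfg$min_clearance, dIdt, use_cache = TRUE)$aad
        }, 1)
        n_evals <- n_evals + 2L
        best <- which.min(cand_aad)
        if (cand_aad[best] < cur_aad) {
          cur_pose <- cand_poses[[best]]
          cur_aad <- cand_aad[best]
          add(passes, var, cur_pose, cur_aad)
        }
      }
    }
    if (aad_at_pass_start - cur_aad < cfg$saturation_tol) break
    if (passes >= cfg$max_passes) break
  }
  structure(list(iterations = do.call(rbind, rows), poses = poses,
                 accepted_index = length(poses), df_history = numeric(0),
                 passes = passes, n_evals = n_evals,
                 saturated = aad_at_pass_start - cur_aad < cfg$saturation_tol),
            class = "ip_trace")
}

#' @export
print.ip_trace <- function(x, ...) {
  it <- x$iterations
  cat(sprintf("ip_trace: %d accepted updates over %d passes, AAD %.2f -> %.2f mm\n",
              nrow(it) - 1L, x$passes, it$aad[1], it$aad[x$accepted_index]))
  invisible(x)
}

#' Write a descent trace as CSV (pass,variable,x,y,z,pitch,roll,yaw,aad)
#' @param trace an `ip_trace`.
#' @param path output path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace$iterations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Relative average defocalization of a pose
#'
#' Perturbs every pose variable by +/- the stability steps (1.5 mm /
#' 0.1 rad), re-evaluates the AAD, and averages the ratios
#' `AAD_n / AAD_final` over the unperturbed case (ratio exactly 1) and the
#' 12 perturbations. Infeasible perturbations are skipped with a message;
#' ratios are not clamped at one, so raw means slightly below one are
#' reported as-is.
#'
#' @param system a `forward_system`.
#' @param coil local-frame `coil`.
#' @param pose_final `coil_pose` to assess.
#' @param obs `observation_surface`.
#' @param target 3-vector, mm.
#' @param cfg [search_config()].
#' @param mcfg [metric_config()].
#' @param dIdt pulse strength, A/s.
#' @param aad_final optional precomputed AAD of `pose_final`.
#' @return dimensionless DF_coil.
#' @export
defocalization <- function(system, coil, pose_final, obs, target,
                           cfg = search_config(), mcfg = metric_config(),
                           dIdt = 9.4e7, aad_final = NULL) {
  if (is.null(aad_final)) {
    ev <- evaluate_pose(system, coil, pose_final, obs, target, mcfg,
                        cfg$min_clearance, dIdt, use_cache = TRUE)
    if (!ev$feasible) stop("defocalization: pose is infeasible")
    aad_final <- ev$aad
  }
  if (!is.finite(aad_final) || aad_final <= 0)
    stop("defocalization: AAD_final must be positive")
  ratios <- if (cfg$df_include_unperturbed) 1 else numeric(0)
  n_skipped <- 0L
  for (var in c("x", "y", "z", "pitch", "roll", "yaw")) {
    step <- if (var %in% c("x", "y", "z")) cfg$df_step_linear else cfg$df_step_angular
    for (sgn in c(-1, 1)) {
      p <- pose_set(pose_final, var, pose_get(pose_final, var) + sgn * step)
      ev <- evaluate_pose(system, coil, p, obs, target, mcfg,
                          cfg$min_clearance, dIdt, use_cache = TRUE)
      if (!ev$feasible) {
        n_skipped <- n_skipped + 1L
        next
      }
      ratios <- c(ratios, ev$aad / aad_final)
    }
  }
  if (n_skipped > 0)
    message(sprintf("defocalization: %d infeasible perturbation(s) skipped", n_skipped))
  if (length(ratios) == 0) stop("defocalization: all perturbations infeasible")
  mean(ratios)
}

#' Stability correction of a descent trace
#'
#' When the defocalization at the last accepted iteration reaches the
#' instability limit, the solution is reverted one accepted update (or one
#' whole pass) at a time until `DF < df_limit` holds; `accepted_index` and
#' `df_history` record the checks.
#'
#' @param trace an `ip_trace` from [descend()].
#' @inheritParams defocalization
#' @return the updated `ip_trace`, with attribute `df_final` (the DF at
#'   the accepted iteration).
#' @export
stability_correct <- function(trace, system, coil, obs, target,
                              cfg = search_config(), mcfg = metric_config(),
                              dIdt = 9.4e7) {
  if (length(trace$poses) == 0) stop("stability_correct: empty trace")
  idx <- length(trace$poses)
  df_hist <- numeric(0)
  repeat {
    pose <- trace$poses[[idx]]
    df <- defocalization(system, coil, pose, obs, target, cfg, mcfg, dIdt,
                         aad_final = trace$iterations$aad[idx])
    df_hist <- c(df_hist, df)
    if (df < cfg$df_limit) break
    if (cfg$revert_granularity == "pass") {
      this_pass <- trace$iterations$pass[idx]
      prev <- which(trace$iterations$pass < this_pass)
      if (length(prev) == 0)
        stop("stability_correct: no iteration satisfies the DF limit")
      idx <- max(prev)
    } else {
      idx <- idx - 1L
      if (idx < 1L)
        stop("stability_correct: no iteration satisfies the DF limit")
    }
  }
  trace$accepted_index <- idx
  trace$df_history <- df_hist
  attr(trace, "df_final") <- df_hist[length(df_hist)]
  trace
}

#' Exhaustive grid search (validation oracle)
#'
#' Evaluates every pose on a per-variable offset grid about `pose0` and
#' returns the feasible global minimizer. Grids are capped (5,000 poses by
#' default) because this is the reference oracle, not the production
#' search.
#'
#' @param system a `forward_system`.
#' @param coil local-frame `coil`.
#' @param pose0 `coil_pose` at the grid center.
#' @param obs `observation_surface`.
#' @param target 3-vector, mm.
#' @param grid named list of numeric offset vectors for any of
#'   `x, y, z, pitch, roll, yaw` (offsets are added to `pose0`).
#' @param mcfg [metric_config()].
#' @param cfg [search_config()] (for the clearance constraint).
#' @param max_poses grid-size cap.
#' @param dIdt pulse strength, A/s.
#' @return list with `pose`, `aad`, `n_feasible`, `n_total`.
#' @export
exhaustive_search <- function(system, coil, pose0, obs, target, grid,
                              mcfg = metric_config(), cfg = search_config(),
                              max_poses = 5000L, dIdt = 9.4e7) {
  stopifnot(all(names(grid) %in% c("x", "y", "z", "pitch", "roll", "yaw")))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) > max_poses)
    stop(sprintf("grid has %d poses, exceeding the cap of %d", nrow(combos), max_poses))
  best_aad <- Inf; best_pose <- NULL; n_feas <- 0L
  for (i in seq_len(nrow(combos))) {
    p <- pose0
    for (var in names(grid))
      p <- pose_set(p, var, pose_get(pose0, var) + combos[i, var])
    ev <- evaluate_pose(system, coil, p, obs, target, mcfg,
                        cfg$min_clearance, dIdt, use_cache = TRUE)
    if (!ev$feasible) next
    n_feas <- n_feas + 1L
    if (ev$aad < best_aad) { best_aad <- ev$aad; best_pose <- p }
  }
  if (is.null(best_pose)) stop("exhaustive_search: all grid poses infeasible")
  list(pose = best_pose, aad = best_aad, n_feasible = n_feas,
       n_total = nrow(combos))
}

#' Full inverse-problem pipeline for one target
#'
#' Sulcus-aligned initial placement, initial metrics, sequential
#' coordinate descent, stability correction, defocalization at both the
#' initial and the accepted final pose, and the corrected focality
#' improvement and field loss.
#'
#' @param system a `forward_system` (or a `head_model`, assembled on the
#'   fly).
#' @param coil local-frame `coil`.
#' @param target_set a `target_set` (target + neighbours + observation
#'   nodes).
#' @param obs `observation_surface`.
#' @param cfg [search_config()].
#' @param mcfg [metric_config()].
#' @param wall_normal passed to [sulcus_aligned_pose()].
#' @param dIdt pulse strength, A/s.
#' @return object of class `ip_report`.
#' @export
run_ip <- function(system, coil, target_set, obs, cfg = search_config(),
                   mcfg = metric_config(), wall_normal = "auto",
                   dIdt = 9.4e7) {
  if (inherits(system, "head_model")) system <- assemble_system(system)
  target <- target_set$target
  pose0 <- sulcus_aligned_pose(system$head, target, coil, wall_normal)
  ev0 <- evaluate_pose(system, coil, pose0, obs, target, mcfg,
                       cfg$min_clearance, dIdt)
  if (!ev0$feasible) stop("run_ip: sulcus-aligned pose is infeasible")
  has_nb <- !is.null(target_set$neighbors) && nrow(target_set$neighbors) > 0
  ard0 <- if (has_nb) ard(ev0$field, target_set, mcfg$n_avg_nodes) else NA_real_
  pd0 <- peak_deviation(ev0$field, target, mcfg$peak_percentile)
  df0 <- defocalization(system, coil, pose0, obs, target, cfg, mcfg, dIdt,
                        aad_final = ev0$aad)
  trace <- descend(system, coil, pose0, obs, target, cfg, mcfg, dIdt)
  trace <- stability_correct(trace, system, coil, obs, target, cfg, mcfg, dIdt)
  pose1 <- trace$poses[[trace$accepted_index]]
  ev1 <- evaluate_pose(system, coil, pose1, obs, target, mcfg,
                       cfg$min_clearance, dIdt)
  ard1 <- if (has_nb) ard(ev1$field, target_set, mcfg$n_avg_nodes) else NA_real_
  pd1 <- peak_deviation(ev1$field, target, mcfg$peak_percentile)
  df1 <- attr(trace, "df_final")
  fl <- field_loss(ev0$field, ev1$field, target, mcfg$n_avg_nodes)
  rep <- structure(list(aad_initial = ev0$aad, aad_final = ev1$aad,
                        df_initial = df0, df_final = df1,
                        ard_initial = ard0, ard_final = ard1,
                        field_loss = fl,
                        peak_dev_initial = pd0, peak_dev_final = pd1,
                        improvement = NA_real_,
                        pose_initial = pose0, pose_final = pose1,
                        trace = trace, target = target,
                        config = list(search = unclass(cfg),
                                      metric = unclass(mcfg), dIdt = dIdt)),
                   class = "ip_report")
  rep$improvement <- focality_improvement(rep)
  rep
}

#' @export
print.ip_report <- function(x, ...) {
  cat(sprintf(paste0("ip_report: AAD %.2f -> %.2f mm  DF %.3f -> %.3f  ",
                     "improvement %.1f%%  field loss %.1f%%\n"),
              x$aad_initial, x$aad_final, x$df_initial, x$df_final,
              100 * x$improvement, x$field_loss))
  invisible(x)
}
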