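# Shared fixtures: a nominal adult subject and standard tasks. Solver
# results are memoized package-wide (cached_smooth_effort), so repeated
# use across test files costs one solve each.

nominal_params <- function(gravity = 9.81) {
  anthropometrics_from_body(70, 0.70, gravity = gravity)
}

task_up <- function(duration = 0.40) movement_task(gamma = -pi / 2,
                                                   duration = duration)
task_down <- function(duration = 0.40) movement_task(gamma = pi / 2,
                                                     duration = duration)

sr_of <- function(traj) trajectory_sr(traj)
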