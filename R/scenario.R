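#' Simulation scenario
#'
#' Bundles everything one run needs: the patient model, the controller kind
#' (`"none"`, `"emk"` or `"adaptive"`), its gains and adaptation matrix
#' where applicable, and the integration settings. Untreated scenarios must
#' not carry gains; adaptive scenarios must carry an adaptation gain and an
#' initial estimate.
#'
#' @param name scenario label (single string).
#' @param model a [mood_model()].
#' @param controller `"none"`, `"emk"` or `"adaptive"`.
#' @param gains a [control_gains()] for controlled scenarios.
#' @param gamma an [adaptation_gain()] for adaptive scenarios.
#' @param config a [sim_config()].
#' @param law control-law variant, see [emk_control()].
#' @return An object of class `mood_scenario`.
#' @seealso [scenario_presets()], [load_scenario()], [run_scenario()]
#' @export
scenario <- function(name, model, controller = c("none", "emk", "adaptive"),
                     gains = NULL, gamma = NULL, config,
                     law = c("corrected", "as-printed")) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_invalid("`name` must be a non-empty string")
  }
  if (!inherits(model, "mood_model")) stop_invalid("`model` must be a mood_model")
  controller <- match.arg(controller)
  config <- check_config(config)
  law <- match.arg(law)
  if (controller == "none") {
    if (!is.null(gains) || !is.null(gamma)) {
      stop_invalid("an untreated scenario must not carry control gains")
    }
  } else {
    gains <- check_gains(gains)
  }
  if (controller == "adaptive") {
    gamma <- check_gamma(gamma)
    if (is.null(config$initial_estimate)) {
      stop_invalid("an adaptive scenario requires `initial_estimate`")
    }
  } else if (controller == "emk" && !is.null(gamma)) {
    stop_invalid("`gamma` is only meaningful for adaptive scenarios")
  }
  structure(
    list(name = name, model = model, controller = controller,
         gains = gains, gamma = gamma, config = config, law = law),
    class = "mood_scenario"
  )
}

#' @export
print.mood_scenario <- function(x, ...) {
  cat(sprintf("<mood_scenario> %s: controller = %s, a = %g, b = %g, c = %g\n",
              x$name, x$controller, x$model$a, x$model$b, x$model$c))
  cat(sprintf("  x(0) = (%g, %g), duration = %g, step = %g, method = %s\n",
              x$config$initial_state[1], x$config$initial_state[2],
              x$config$duration, x$config$step, x$config$method))
  if (!is.null(x$gains)) {
    cat(sprintf("  gains: k1 = %g, k2 = %g\n", x$gains$k1, x$gains$k2))
  }
  if (!is.null(x$config$initial_estimate)) {
    cat(sprintf("  initial estimate: (%s)\n",
                paste(format(x$config$initial_estimate), collapse = ", ")))
  }
  invisible(x)
}

#' Bundled reference scenarios
#'
#' Named presets reproducing the package's standard demonstration runs, all
#' for the reference patient (a = 1, b = 2, c = 9) started at
#' `x(0) = (0.5, 0)`:
#'
#' * `figure1-untreated`: no treatment over 40 time units -- the sustained
#'   mood swing.
#' * `figure2-emk`: exact-model-knowledge treatment, gains (1.1, 10), 10
#'   time units.
#' * `figure5-adaptive`: adaptive treatment, gains (1.22, 10), adaptation
#'   gain 0.1 I, initial estimate (6, 2.5, 5), 10 time units.
#' * `figure11-reestimation`: the adaptive scenario run for 30 time units
#'   so the steady-state parameter estimates can be read off.
#'
#' @return Named list of [scenario()] objects.
#' @export
scenario_presets <- function() {
  ref <- mood_model(a = 1, b = 2, c = 9)
  x0 <- c(0.5, 0)
  list(
    "figure1-untreated" = scenario(
      "figure1-untreated", ref, "none",
      config = sim_config(duration = 40, initial_state = x0)
    ),
    "figure2-emk" = scenario(
      "figure2-emk", ref, "emk", gains = control_gains(1.1, 10),
      config = sim_config(duration = 10, initial_state = x0)
    ),
    "figure5-adaptive" = scenario(
      "figure5-adaptive", ref, "adaptive", gains = control_gains(1.22, 10),
      gamma = adaptation_gain(0.1),
      config = sim_config(duration = 10, initial_state = x0,
                          initial_estimate = c(6, 2.5, 5))
    ),
    "figure11-reestimation" = scenario(
      "figure11-reestimation", ref, "adaptive",
      gains = control_gains(1.22, 10), gamma = adaptation_gain(0.1),
      config = sim_config(duration = 30, initial_state = x0,
                          initial_estimate = c(6, 2.5, 5))
    )
  )
}

scenario_keys <- list(
  top = c("name", "model", "controller", "gains", "adaptation", "init", "sim",
          "law"),
  model = c("a", "b", "c"),
  gains = c("k1", "k2"),
  adaptation = "gamma",
  init = c("state", "estimate"),
  sim = c("duration", "step", "method", "thin")
)

check_keys <- function(x, section, where) {
  if (is.null(x)) return(invisible())
  if (!is.list(x)) {
    stop_invalid(sprintf("config section `%s` must be a mapping", where))
  }
  unknown <- setdiff(names(x), scenario_keys[[section]])
  if (length(unknown)) {
    stop_invalid(
      sprintf("unknown key%s in `%s`: %s", if (length(unknown) > 1) "s" else "",
              where, paste(unknown, collapse = ", ")),
      class = "moodswing_unknown_key"
    )
  }
  invisible()
}

need_key <- function(x, key, where) {
  if (is.null(x[[key]])) {
    stop_invalid(sprintf("missing required key `%s` in `%s`", key, where),
                 class = "moodswing_missing_key")
  }
  x[[key]]
}

#' Load a scenario from a YAML configuration file
#'
#' Parses and fully validates a scenario description. The dialect is YAML
#' with the nested sections `model` (a, b, c), `controller`
#' (none/emk/adaptive), `gains` (k1, k2), `adaptation` (gamma: scalar or
#' 3x3 row list), `init` (state, estimate) and `sim` (duration, step,
#' method, thin); see the bundled example under
#' `system.file("extdata", "emk-example.yaml", package = "moodswing")`.
#' Unknown keys anywhere are rejected by name; missing required keys and
#' constraint violations raise distinct, message-bearing errors.
#'
#' @param path path to the YAML file.
#' @return A validated [scenario()] object.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("config file not found: %s", path))
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop_invalid(sprintf("cannot parse config %s: %s", path,
                           conditionMessage(e)),
                   class = "moodswing_parse_error")
    }
  )
  if (!is.list(raw)) {
    stop_invalid("config must be a YAML mapping",
                 class = "moodswing_parse_error")
  }
  check_keys(raw, "top", "<top level>")
  for (sec in c("model", "gains", "adaptation", "init", "sim")) {
    check_keys(raw[[sec]], sec, sec)
  }
  mdl <- need_key(raw, "model", "<top level>")
  model <- mood_model(need_key(mdl, "a", "model"),
                      need_key(mdl, "b", "model"),
                      need_key(mdl, "c", "model"))
  controller <- need_key(raw, "controller", "<top level>")
  if (!is.character(controller) || length(controller) != 1L ||
      !controller %in% c("none", "emk", "adaptive")) {
    stop_invalid("`controller` must be one of none, emk, adaptive")
  }
  gains <- NULL
  if (!is.null(raw$gains)) {
    gains <- control_gains(need_key(raw$gains, "k1", "gains"),
                           need_key(raw$gains, "k2", "gains"))
  }
  gamma <- NULL
  if (!is.null(raw$adaptation)) {
    g <- need_key(raw$adaptation, "gamma", "adaptation")
    if (is.list(g)) g <- do.call(rbind, g)
    gamma <- adaptation_gain(g)
  }
  init <- raw$init
  state <- if (is.null(init$state)) c(0.5, 0) else unlist(init$state)
  estimate <- if (is.null(init$estimate)) NULL else unlist(init$estimate)
  sm <- need_key(raw, "sim", "<top level>")
  config <- sim_config(
    duration = need_key(sm, "duration", "sim"),
    step = if (is.null(sm$step)) 1e-3 else sm$step,
    method = if (is.null(sm$method)) "rk4-fixed" else sm$method,
    initial_state = state,
    initial_estimate = estimate,
    thin = if (is.null(sm$thin)) 1L else sm$thin
  )
  scenario(
    name = if (is.null(raw$name)) basename(path) else raw$name,
    model = model, controller = controller, gains = gains, gamma = gamma,
    config = config,
    law = if (is.null(raw$law)) "corrected" else raw$law
  )
}

#' Run a scenario
#'
#' Dispatches to [simulate_untreated()], [simulate_emk()] or
#' [simulate_adaptive()] according to the scenario's controller kind.
#'
#' @param sc a [scenario()].
#' @return A `mood_trajectory`.
#' @examples
#' tr <- run_scenario(scenario_presets()[["figure2-emk"]])
#' oscillation_metrics(tr)
#' @export
run_scenario <- function(sc) {
  if (!inherits(sc, "mood_scenario")) {
    stop_invalid("`sc` must be a mood_scenario")
  }
  switch(sc$controller,
    none = simulate_untreated(sc$model, sc$config),
    emk = simulate_emk(sc$model, sc$gains, sc$config, law = sc$law),
    adaptive = simulate_adaptive(sc$model, sc$gains, sc$gamma, sc$config,
                                 law = sc$law)
  )
}
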