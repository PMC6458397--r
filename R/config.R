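# Declarative scenario configuration (YAML) ------------------------------
#
# A run config either names a built-in scenario (with optional builder
# overrides) or defines a custom world in full. Validation failures name
# the offending key path; transitions and emissions must normalise exactly.

builtin_scenarios <- function() {
  list(
    social_response = build_social_response,
    imitation = build_imitation,
    transfer = build_transfer,
    sequence = build_sequence,
    avoidance = build_avoidance
  )
}

config_stop <- function(where, ...) {
  stop("config error at `", where, "`: ", ..., call. = FALSE)
}

#' Parse a run configuration
#'
#' Reads a YAML run configuration and returns the validated run settings
#' plus the scenario they select. Two forms are accepted: a built-in
#' scenario by name with optional parameter overrides
#' (\code{scenario: transfer}, \code{overrides: {v_prior: 5}}), or a fully
#' custom scenario (\code{elements}, \code{behaviours}, \code{params},
#' \code{priors}, \code{world}, \code{trace}). Learning parameters default
#' to \code{alpha_v = 0.1, alpha_w = 0.1, beta = 1} when absent. A seed is
#' mandatory: runs are never silently nondeterministic. Unknown keys are
#' rejected; every validation failure names the offending key.
#'
#' @param path Path to a YAML file (or use \code{text}).
#' @param text YAML source as a string.
#' @return A list with \code{config} (run settings: \code{n_replicates},
#'   \code{n_trials}, \code{seed}, \code{output_dir}, \code{emit_plots},
#'   \code{arms}) and \code{scenario} (a validated scenario object).
#' @examples
#' cfg <- parse_run_config(text = "
#' scenario: social_response
#' seed: 1
#' n_replicates: 10
#' ")
#' cfg$scenario
#' @export
parse_run_config <- function(path = NULL, text = NULL) {
  stopifnot(xor(is.null(path), is.null(text)))
  raw <- if (is.null(text)) {
    yaml::read_yaml(path)
  } else {
    yaml::yaml.load(text)
  }
  if (!is.list(raw)) config_stop("<top>", "expected a mapping")
  run_keys <- c("seed", "n_replicates", "n_trials", "output_dir",
                "emit_plots", "arms")
  builtin_keys <- c("scenario", "overrides")
  custom_keys <- c("name", "elements", "behaviours", "params", "priors",
                   "world", "trace")
  unknown <- setdiff(names(raw), c(run_keys, builtin_keys, custom_keys))
  if (length(unknown)) {
    config_stop(unknown[[1]], "unknown key")
  }
  is_builtin <- !is.null(raw$scenario)
  if (is_builtin && any(custom_keys %in% names(raw))) {
    config_stop("scenario", "give either a built-in `scenario` name or a ",
                "custom world definition, not both")
  }
  if (!is_builtin && !all(c("elements", "behaviours", "world") %in% names(raw))) {
    config_stop("<top>", "a custom scenario needs `elements`, `behaviours` ",
                "and `world` (or name a built-in under `scenario`)")
  }
  if (is.null(raw$seed)) config_stop("seed", "a seed is required")
  if (!is.numeric(raw$seed) || raw$seed != round(raw$seed)) {
    config_stop("seed", "must be an integer")
  }
  scenario <- if (is_builtin) {
    builders <- builtin_scenarios()
    if (!raw$scenario %in% names(builders)) {
      config_stop("scenario", "unknown scenario '", raw$scenario,
                  "'; built-ins: ", paste(names(builders), collapse = ", "))
    }
    overrides <- raw$overrides %||% list()
    builder <- builders[[raw$scenario]]
    bad <- setdiff(names(overrides), names(formals(builder)))
    if (length(bad)) {
      config_stop(paste0("overrides.", bad[[1]]),
                  "not a parameter of scenario '", raw$scenario, "'")
    }
    do.call(builder, overrides)
  } else {
    scenario_from_config(raw)
  }
  defaults <- scenario$defaults
  config <- list(
    seed = as.integer(raw$seed),
    n_replicates = as.integer(raw$n_replicates %||% defaults$n_replicates),
    n_trials = as.integer(raw$n_trials %||% defaults$n_trials),
    output_dir = raw$output_dir %||% ".",
    emit_plots = isTRUE(raw$emit_plots),
    arms = raw$arms %||% names(scenario$arms)
  )
  bad_arms <- setdiff(config$arms, names(scenario$arms))
  if (length(bad_arms)) {
    config_stop("arms", "unknown arm '", bad_arms[[1]], "'")
  }
  if (config$n_replicates < 1 || config$n_trials < 1) {
    config_stop("n_replicates/n_trials", "must be positive")
  }
  list(config = config, scenario = scenario)
}

#' Build a scenario from a declarative description
#'
#' Turns the custom-scenario form of the run configuration (already parsed
#' from YAML into lists) into a validated scenario object. Exposed mainly
#' for programmatic construction and testing; \code{\link{parse_run_config}}
#' is the usual entry point.
#'
#' @param raw Named list with \code{elements}, \code{behaviours},
#'   \code{world}, and optional \code{name}, \code{params}, \code{priors},
#'   \code{trace}, \code{n_replicates}, \code{n_trials}.
#' @return A scenario object with a single arm \code{"custom"}.
#' @export
scenario_from_config <- function(raw) {
  els <- raw$elements
  if (!is.list(els) || is.null(names(els))) {
    config_stop("elements", "expected a mapping of element name to ",
                "{u, social}")
  }
  u <- vapply(names(els), function(nm) {
    spec <- els[[nm]]
    if (!is.list(spec) || is.null(spec$u) || !is.numeric(spec$u)) {
      config_stop(paste0("elements.", nm), "needs a numeric `u`")
    }
    spec$u
  }, numeric(1))
  social <- vapply(els, function(spec) isTRUE(spec$social), logical(1))
  elements <- element_table(names(els), unname(u), unname(social))
  behaviours <- as.character(raw$behaviours)
  if (length(behaviours) < 2L) {
    config_stop("behaviours", "need at least two behaviours")
  }
  par_raw <- raw$params %||% list()
  bad_par <- setdiff(names(par_raw), c("alpha_v", "alpha_w", "beta"))
  if (length(bad_par)) config_stop(paste0("params.", bad_par[[1]]), "unknown")
  params <- learning_parameters(
    alpha_v = par_raw$alpha_v %||% 0.1,
    alpha_w = par_raw$alpha_w %||% 0.1,
    beta = par_raw$beta %||% 1
  )
  v_prior <- NULL
  w_prior <- NULL
  if (!is.null(raw$priors)) {
    bad_pri <- setdiff(names(raw$priors), c("v", "w"))
    if (length(bad_pri)) config_stop(paste0("priors.", bad_pri[[1]]), "unknown")
    if (length(raw$priors$v)) {
      v_prior <- do.call(rbind, lapply(raw$priors$v, function(e) {
        if (is.null(e$element) || is.null(e$behaviour) || is.null(e$value)) {
          config_stop("priors.v", "each entry needs element, behaviour, value")
        }
        data.frame(element = e$element, behaviour = e$behaviour,
                   value = e$value)
      }))
    }
    if (length(raw$priors$w)) {
      w_prior <- unlist(raw$priors$w)
    }
  }
  world_raw <- raw$world
  if (is.null(world_raw$states) || is.null(world_raw$start)) {
    config_stop("world", "needs `states` and `start`")
  }
  states <- lapply(names(world_raw$states), function(nm) {
    st <- world_raw$states[[nm]]
    where <- paste0("world.states.", nm)
    if (isTRUE(st$terminal)) return(end_state())
    ems <- lapply(st$emissions, function(e) {
      if (is.null(e$prob) || is.null(e$stimulus)) {
        config_stop(where, "each emission needs `prob` and `stimulus`")
      }
      emission(e$prob, unlist(e$stimulus),
               key = e$key %||% paste(unlist(e$stimulus), collapse = "+"))
    })
    trs <- list()
    for (tr in st$transitions) {
      if (is.null(tr$behaviour) || is.null(tr$outcomes)) {
        config_stop(where, "each transition needs `behaviour` and `outcomes`")
      }
      key <- tr$context %||%
        if (length(ems) == 1L) ems[[1]]$key else
          config_stop(where, "transitions need `context` when a state has ",
                      "several emissions")
      outs <- lapply(tr$outcomes, function(o) {
        if (is.null(o$prob) || is.null(o[["next"]])) {
          config_stop(where, "each outcome needs `prob` and `next`")
        }
        obs <- lapply(o$observations %||% list(), function(ob) {
          list(prob = ob$prob %||% 1, from = unlist(ob$from),
               to = unlist(ob$to))
        })
        outcome(o$prob,
                if (is.null(o$consequence)) NULL else unlist(o$consequence),
                o[["next"]], flags = as.character(o$flags %||% character()),
                observations = obs)
      })
      trs[[paste0(key, "::", tr$behaviour)]] <- outs
    }
    world_state(emissions = ems, transitions = trs)
  })
  names(states) <- names(world_raw$states)
  start <- world_raw$start
  world <- world_machine(states, stats::setNames(as.numeric(start),
                                                 names(start)))
  mem <- tryCatch(
    make_memory(elements, behaviours, params, v_prior = v_prior,
                w_prior = w_prior),
    error = function(e) config_stop("priors", conditionMessage(e))
  )
  trace <- lapply(seq_along(raw$trace %||% list()), function(i) {
    q <- raw$trace[[i]]
    where <- paste0("trace[", i, "]")
    switch(q$type %||% config_stop(where, "needs `type`"),
      p = trace_p_single(unlist(q$stimulus), q$behaviour),
      v = trace_v(q$element, q$behaviour),
      w = trace_w(q$element),
      config_stop(where, "unknown trace type '", q$type, "'")
    )
  })
  if (!length(trace)) {
    # default: response distribution entries for the first state's emission
    first_em <- states[[names(world$start)[[1]]]]$emissions[[1]]
    trace <- lapply(behaviours, function(b) {
      trace_p_single(first_em$stimulus, b)
    })
  }
  tryCatch(
    new_scenario(
      raw$name %||% "custom", elements, behaviours, params,
      arms = list(custom = new_arm(world, mem, trace)),
      defaults = list(n_replicates = raw$n_replicates %||% 100,
                      n_trials = raw$n_trials %||% 100)
    ),
    error = function(e) config_stop("world", conditionMessage(e))
  )
}
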