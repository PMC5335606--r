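#' Compile a demographic model into an executable event schedule
#'
#' Translates a (model, parameters, design) triple into the backwards-in-time
#' event list consumed by [simulate_genealogy()]. Two demes exist, Sardinia
#' and Continent, with present sizes `Ncs` and `Ncn`. Looking backwards:
#'
#' * at the Neolithic migration time (6,000 years / generation time = 200
#'   generations by default) a fraction `P` of Sardinian lineages moves to
#'   the Continent deme (no event is emitted when P = 0), and both demes
#'   change to their ancient sizes (`Ncs` to `Nas`, `Ncn` to `Nan`);
#' * `bottleneck_window` generations before the colonization of Sardinia the
#'   Sardinian size drops to `Nas / rs` (the founder bottleneck; `rs = 1`
#'   means no bottleneck);
#' * at the colonization time `Tcol` (converted to generations) every
#'   Sardinian lineage moves to the Continent deme, which then remains the
#'   single ancestral deme.
#'
#' Sample groups activate at their sampling ages converted to generations
#' (rounded): with the default design MS at 0, MN at 257, EN at 290 and MSS
#' at 333 generations.
#'
#' @param model model label; under `"continuity"` P must be 0 and under
#'   `"discontinuity"` P must be 1 (use [draw_parameters()]).
#' @param params a [param_draw()].
#' @param design a [study_design()].
#' @param migration_age_yBP age of the Neolithic migration pulse, years BP.
#' @param bottleneck_window length of the founder bottleneck, generations.
#' @return An object of class `event_schedule`: a sorted event table, the
#'   initial deme sizes, and the sample activation table.
#' @export
build_schedule <- function(model, params, design = study_design(),
                           migration_age_yBP = 6000,
                           bottleneck_window = 10) {
  check_model(model)
  if (!inherits(params, "param_draw")) params <- do.call(param_draw, params)
  if (model == "continuity" && params$P != 0)
    stop("continuity requires P = 0")
  if (model == "discontinuity" && params$P != 1)
    stop("discontinuity requires P = 1")
  oldest <- max(design$populations$age_yBP)
  if (params$Tcol <= oldest)
    stop("colonization postdates sample: Tcol = ", params$Tcol,
         " yBP must exceed the oldest sampling age ", oldest, " yBP")

  g <- design$generation_time
  T_mig <- round(migration_age_yBP / g)
  T_col <- round(params$Tcol / g)
  mig <- params$P > 0
  events <- data.frame(
    time = c(T_mig, T_mig, if (mig) T_mig,
             max(T_col - bottleneck_window, T_mig), T_col),
    type = c("resize", "resize", if (mig) "move", "resize", "move"),
    deme = c("sardinia", "continent", if (mig) "sardinia",
             "sardinia", "sardinia"),
    dest = c(NA, NA, if (mig) "continent", NA, "continent"),
    size = c(params$Nas, params$Nan, if (mig) NA,
             params$Nas / params$rs, NA),
    frac = c(NA, NA, if (mig) params$P, NA, 1),
    stringsAsFactors = FALSE)
  events <- events[order(events$time,
                         match(events$type, c("resize", "move"))), ]
  rownames(events) <- NULL

  samples <- design_samples(design)
  if (any(samples$time >= T_col & samples$deme == "sardinia"))
    stop("colonization postdates sample: a Sardinian sample activates at ",
         "or after the colonization merge")

  structure(list(model = model, params = params, events = events,
                 init_sizes = c(sardinia = params$Ncs,
                                continent = params$Ncn),
                 samples = samples, T_mig = T_mig, T_col = T_col),
            class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat("Event schedule (", x$model, "): ", nrow(x$samples),
      " samples, events:\n", sep = "")
  print(x$events, row.names = FALSE)
  invisible(x)
}
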