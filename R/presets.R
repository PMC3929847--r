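#' Benchmark presets for the four rejection-rate tables
#'
#' Returns the [scenario_spec()] for one cell of the simulation benchmark.
#' The four tables share the five-gene pathway G1(12)...G5(2) with MAF 0.3
#' and differ in sample size, LD strength and weighting:
#' table 1: n = 200, D = 0.15, gene-size weights;
#' table 2: n = 400, D = 0.20, gene-size weights;
#' table 3: n = 400, D = 0.15, gene-size weights;
#' table 4: n = 200, D = 0.20, flat weights (no size correction).
#'
#' The full-scale profile uses 1000 replicates with 1000 permutations per
#' replicate; the desk-scale profile (`profile = "desk"`) uses 500
#' replicates with 300 permutations, which leaves every rate within about
#' 0.02 (binomial SE) of the full run at a fraction of the cost.
#'
#' @param table benchmark table number, 1-4.
#' @param case disease case `"I"`..`"VI"`.
#' @param beta shared effect size (0 for the Type I error row).
#' @param profile `"full"` (reps = 1000, m = 1000) or `"desk"`
#'   (reps = 500, m = 300).
#' @param seed master seed.
#' @param ... overrides passed on to [scenario_spec()].
#' @return a [scenario_spec()].
#' @export
table_preset <- function(table, case = "I", beta = 0,
                         profile = c("full", "desk"), seed = 1L, ...) {
  profile <- match.arg(profile)
  stopifnot(table %in% 1:4)
  layout <- list(
    list(n = 200, D = 0.15, weighting = "gene_size"),
    list(n = 400, D = 0.20, weighting = "gene_size"),
    list(n = 400, D = 0.15, weighting = "gene_size"),
    list(n = 200, D = 0.20, weighting = "flat")
  )[[table]]
  sizes <- if (profile == "full") c(reps = 1000L, m = 1000L)
           else c(reps = 500L, m = 300L)
  args <- list(
    ld_config = ld_config(n_subjects = layout$n, D = layout$D),
    case = case, beta = beta, reps = sizes[["reps"]],
    m_perm = sizes[["m"]], weighting = layout$weighting, seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(scenario_spec, args)
}
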