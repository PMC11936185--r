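#' Run the full analysis and write every output
#'
#' Executes the deterministic base case, the one-way sensitivity analysis
#' and the probabilistic sensitivity analysis, writing all tabular outputs
#' (cohort traces, per-arm cost breakdowns, the incremental comparison,
#' tornado table, PSA draws, acceptability curve), a human-readable summary
#' and, last, a JSON run manifest. The manifest records the package
#' version, deck checksum, seed and output list, and echoes the
#' design-decision toggles (half-cycle setting, cisplatin fraction,
#' treatment cap, PSA spread convention) so a reproduction run is
#' self-describing.
#'
#' @param deck A parameter deck.
#' @param seed RNG seed for the PSA.
#' @param out_dir Output directory (created if needed; must be writable).
#' @param iterations PSA iterations; 10,000 in the reference configuration.
#' @param plots Also write PNG figures (cost-effectiveness plane, tornado,
#'   acceptability curve)?
#' @return The manifest (a list), invisibly; also written as
#'   \code{manifest.json}.
#' @export
run_all <- function(deck = base_deck(), seed = 1, out_dir,
                    iterations = 10000, plots = FALSE) {
  validate_deck(deck)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory is not writable: ", out_dir)
  unlink(probe)
  outputs <- character(0)
  emit <- function(name) {
    outputs <<- c(outputs, name)
    file.path(out_dir, name)
  }

  res <- run_cea(deck, keep_traces = TRUE)
  for (arm in names(res$arms))
    write_trace(res$arms[[arm]]$trace, emit(paste0("trace_", arm, ".csv")))
  breakdown <- do.call(rbind, lapply(res$arms, function(a)
    data.frame(arm = a$arm, category = names(a$breakdown),
               cost = unname(a$breakdown),
               total_cost = a$cost, qalys = a$qalys,
               life_years = a$life_years)))
  utils::write.csv(breakdown, emit("arm_results.csv"), row.names = FALSE)
  write_ce_result(res$incremental, emit("incremental.csv"))

  torn <- one_way_sensitivity(deck)
  utils::write.csv(as.data.frame(torn)[
    , c("parameter", "icer_low", "icer_high", "swing")],
    emit("tornado.csv"), row.names = FALSE)

  psa <- run_psa(deck, iterations = iterations, seed = seed)
  utils::write.csv(psa$draws, emit("psa_draws.csv"), row.names = FALSE)
  utils::write.csv(ceac(psa), emit("ceac.csv"), row.names = FALSE)

  summary_path <- emit("summary.txt")
  con <- file(summary_path, "w")
  sink(con)
  print(res)
  cat("\n")
  print(psa)
  cat("\nRun settings: half_cycle=", deck$settings$half_cycle,
      ", cisplatin_fraction=", deck$regimen$cisplatin_fraction,
      ", max_treatment_cycles=", deck$settings$max_treatment_cycles,
      ", PSA sd convention = (high - low)/3.92\n", sep = "")
  sink()
  close(con)

  if (plots) {
    png_to <- function(name, expr) {
      grDevices::png(emit(name), width = 900, height = 700)
      on.exit(grDevices::dev.off(), add = TRUE)
      force(expr)
    }
    png_to("ce_plane.png", plot(psa))
    png_to("tornado.png", plot(torn))
    png_to("ceac.png", {
      cc <- ceac(psa)
      graphics::plot(cc$wtp, cc$probability, type = "l",
                     xlab = "Willingness-to-pay ($/QALY)",
                     ylab = "P(cost-effective)",
                     main = "Cost-effectiveness acceptability curve")
      graphics::abline(v = deck$settings$wtp, lty = 2)
    })
  }

  manifest <- list(
    package = "psmcea",
    version = as.character(utils::packageVersion("psmcea")),
    deck_checksum = deck_checksum(deck),
    seed = seed,
    iterations = iterations,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    settings = list(
      half_cycle = deck$settings$half_cycle,
      cisplatin_fraction = deck$regimen$cisplatin_fraction,
      max_treatment_cycles = deck$settings$max_treatment_cycles,
      psa_sd_rule = "(high - low) / 3.92"
    ),
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
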