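#' One-way (tornado) sensitivity analysis
#'
#' Reruns the full deterministic model with each parameter set to its low
#' and high bound in turn, all other inputs at base, and records the ICER at
#' each bound. Rows are sorted by descending swing
#' \code{|ICER_high - ICER_low|}.
#'
#' @param deck A parameter deck.
#' @param specs Parameter table as from [param_specs()] (the default).
#' @return A \code{cea_tornado} data frame: \code{parameter},
#'   \code{icer_low}, \code{icer_high}, \code{swing}, \code{nmb_low},
#'   \code{nmb_high}, with attribute \code{base_icer}.
#' @examples
#' \donttest{
#' torn <- one_way_sensitivity(base_deck())
#' head(torn, 3)
#' }
#' @export
one_way_sensitivity <- function(deck, specs = param_specs(deck)) {
  icer_at <- function(name, value) {
    res <- run_cea(set_param(deck, name, value))
    c(res$incremental$icer, res$incremental$nmb)
  }
  lo <- mapply(icer_at, specs$name, specs$low)
  hi <- mapply(icer_at, specs$name, specs$high)
  out <- data.frame(
    parameter = specs$name,
    icer_low = lo[1L, ], icer_high = hi[1L, ],
    swing = abs(hi[1L, ] - lo[1L, ]),
    nmb_low = lo[2L, ], nmb_high = hi[2L, ]
  )
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  base <- run_cea(deck)
  structure(out, base_icer = base$incremental$icer,
            wtp = deck$settings$wtp,
            class = c("cea_tornado", "data.frame"))
}

#' @export
plot.cea_tornado <- function(x, n = min(nrow(x), 12L), ...) {
  x <- x[seq_len(n), ]
  base <- attr(x, "base_icer")
  o <- rev(seq_len(n))
  graphics::par(mar = c(4, 14, 2, 1))
  lo <- pmin(x$icer_low, x$icer_high)
  hi <- pmax(x$icer_low, x$icer_high)
  graphics::plot(NULL, xlim = range(c(lo, hi, base)), ylim = c(0.5, n + 0.5),
                 yaxt = "n", xlab = "ICER ($/QALY)", ylab = "",
                 main = "One-way sensitivity", ...)
  graphics::axis(2, at = o, labels = x$parameter, las = 1, cex.axis = 0.7)
  graphics::rect(lo, o - 0.35, hi, o + 0.35, col = "steelblue")
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

## ---- PSA -------------------------------------------------------------------

# Method-of-moments gamma/beta samplers. The published ranges are read as
# 95% intervals, sd = (high - low) / 3.92. Beta parameters whose base lies
# outside (0, 1) (e.g. body surface area) are drawn as a scaled beta on
# [low, high]. An infeasible beta moment match (sd^2 >= m(1-m)) falls back
# to a shrunken sd with a warning.
draw_param <- function(n, base, low, high, dist) {
  sd <- (high - low) / 3.92
  if (dist == "fixed" || sd <= 0) return(rep(base, n))
  if (dist == "gamma") {
    shape <- (base / sd)^2
    return(stats::rgamma(n, shape = shape, rate = base / sd^2))
  }
  if (dist == "beta") {
    if (base > 0 && base < 1 && low >= 0 && high <= 1) {
      m <- base
      scale01 <- FALSE
    } else {
      m <- (base - low) / (high - low)
      scale01 <- TRUE
      sd <- sd / (high - low)
    }
    vmax <- m * (1 - m)
    if (sd^2 >= vmax) {
      warning("beta moment match infeasible for base ", base,
              "; shrinking sd")
      sd <- 0.95 * sqrt(vmax)
    }
    nu <- vmax / sd^2 - 1
    x <- stats::rbeta(n, shape1 = m * nu, shape2 = (1 - m) * nu)
    return(if (scale01) low + (high - low) * x else x)
  }
  stop("unknown PSA distribution '", dist, "'")
}

#' Draw one probabilistic parameter deck
#'
#' Samples every gamma/beta parameter in \code{specs} (independently,
#' method-of-moments with mean = base and sd = (high - low)/3.92) and
#' returns the deck with those values substituted. Uses the current RNG
#' stream; seed management belongs to the caller ([run_psa()] seeds once
#' per run).
#'
#' @param deck A parameter deck.
#' @param specs Parameter table as from [param_specs()].
#' @return A sampled deck.
#' @export
sample_psa_deck <- function(deck, specs = param_specs(deck)) {
  draws <- mapply(draw_param, 1L, specs$base, specs$low, specs$high,
                  specs$dist)
  for (i in seq_len(nrow(specs)))
    deck <- set_param(deck, specs$name[i], draws[i])
  deck
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo PSA: for each iteration a full parameter deck is drawn
#' (gamma costs, beta probabilities/utilities; survival parameters fixed),
#' both arms are run and the incremental pair recorded. Reproducible given
#' the seed. A failing draw is recorded as \code{NA} and excluded from
#' summaries with a warning, never aborting the run; draw order is fixed so
#' the iteration-to-random-stream mapping is stable.
#'
#' @param deck A parameter deck.
#' @param iterations Number of Monte-Carlo draws (>= 1); 10,000 in the
#'   reference configuration.
#' @param seed Integer RNG seed.
#' @param specs Parameter table; defaults to [param_specs()].
#' @return A \code{psa_result}: list with \code{draws} (data frame:
#'   \code{iteration}, \code{d_cost}, \code{d_qaly}, \code{nmb},
#'   \code{acceptable}), \code{acceptability} (fraction of draws with
#'   NMB >= 0 at the deck WTP), \code{wtp}, \code{seed},
#'   \code{iterations}, \code{n_failed}.
#' @examples
#' \donttest{
#' psa <- run_psa(base_deck(), iterations = 200, seed = 1)
#' psa$acceptability
#' }
#' @export
run_psa <- function(deck, iterations = 10000, seed = 1,
                    specs = param_specs(deck)) {
  if (iterations < 1) stop("iterations must be >= 1")
  set.seed(seed)
  npar <- nrow(specs)
  # draw matrix first: iteration i uses row i regardless of downstream
  # failures, keeping the draw-index/stream mapping stable
  draws <- matrix(NA_real_, nrow = iterations, ncol = npar)
  for (j in seq_len(npar))
    draws[, j] <- draw_param(iterations, specs$base[j], specs$low[j],
                             specs$high[j], specs$dist[j])
  paths <- strsplit(specs$name, ".", fixed = TRUE)
  d_cost <- d_qaly <- rep(NA_real_, iterations)
  for (i in seq_len(iterations)) {
    di <- deck
    for (j in seq_len(npar)) di[[paths[[j]]]] <- draws[i, j]
    res <- tryCatch({
      a <- run_arm(di, "tislelizumab")
      b <- run_arm(di, "chemotherapy")
      c(a$cost - b$cost, a$qalys - b$qalys)
    }, error = function(e) c(NA_real_, NA_real_))
    d_cost[i] <- res[1L]
    d_qaly[i] <- res[2L]
  }
  n_failed <- sum(is.na(d_cost))
  if (n_failed > 0)
    warning(n_failed, " of ", iterations,
            " PSA draws failed and were excluded")
  wtp <- deck$settings$wtp
  nmb <- net_monetary_benefit(d_cost, d_qaly, wtp)
  acceptable <- nmb >= 0
  structure(
    list(
      draws = data.frame(iteration = seq_len(iterations),
                         d_cost = d_cost, d_qaly = d_qaly,
                         nmb = nmb, acceptable = acceptable),
      acceptability = mean(acceptable, na.rm = TRUE),
      wtp = wtp, seed = seed, iterations = iterations,
      n_failed = n_failed,
      param_means = stats::setNames(colMeans(draws), specs$name)
    ),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  ok <- stats::complete.cases(x$draws[, c("d_cost", "d_qaly")])
  cat("Probabilistic sensitivity analysis\n")
  cat("  iterations:", x$iterations, " (failed:", x$n_failed, ")\n")
  cat("  seed:", x$seed, "\n")
  cat("  mean d_cost: $",
      formatC(mean(x$draws$d_cost[ok]), format = "f", digits = 2,
              big.mark = ","), "\n", sep = "")
  cat("  mean d_QALY: ",
      formatC(mean(x$draws$d_qaly[ok]), format = "f", digits = 4),
      "\n", sep = "")
  cat("  P(cost-effective at WTP $",
      formatC(x$wtp, format = "f", digits = 2, big.mark = ","), "): ",
      formatC(100 * x$acceptability, format = "f", digits = 2), "%\n",
      sep = "")
  invisible(x)
}

#' @export
plot.psa_result <- function(x, ...) {
  ok <- stats::complete.cases(x$draws[, c("d_cost", "d_qaly")])
  d <- x$draws[ok, ]
  graphics::plot(d$d_qaly, d$d_cost, pch = 16, cex = 0.3,
                 col = ifelse(d$acceptable, "forestgreen", "firebrick"),
                 xlab = "Incremental QALYs", ylab = "Incremental cost ($)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(a = 0, b = x$wtp, lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey70")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on a grid, the fraction of PSA draws
#' with non-negative net monetary benefit at that value. Monotonicity is
#' not forced.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Non-empty numeric grid of WTP values; defaults to 0 to
#'   twice the deck WTP in 50 steps.
#' @return A data frame with columns \code{wtp} and \code{probability}.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 2 * psa$wtp, length.out = 51)) {
  if (length(wtp_grid) == 0) stop("wtp_grid must be non-empty")
  ok <- stats::complete.cases(psa$draws[, c("d_cost", "d_qaly")])
  d <- psa$draws[ok, ]
  if (nrow(d) == 0) stop("no successful PSA draws")
  prob <- vapply(
    wtp_grid,
    function(l) mean(net_monetary_benefit(d$d_cost, d$d_qaly, l) >= 0),
    numeric(1L)
  )
  data.frame(wtp = wtp_grid, probability = prob)
}
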