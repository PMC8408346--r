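# Synthetic six-metric quality profiles: a latent per-file badness drives
# all metrics monotonically (with configurable noise), or metrics are drawn
# independently - the two regimes needed to probe the flag-consistency
# diagnostics.

# baseline (best) value and span (drop from best to worst) per metric,
# chosen so each metric crosses its default threshold along the badness axis
.cistrome_ranges <- data.frame(
  metric = c(
    "FASTQC", "UniquelyMappedRatio", "PBC", "FRiP",
    "PeaksUnionDHSRatio", "PeaksFoldChangeAbove10"
  ),
  best = c(38, 0.98, 0.99, 0.05, 0.95, 1500),
  span = c(22, 0.7, 0.5, 0.049, 0.6, 1480),
  floor = c(2, 0, 0, 0, 0, 0),
  ceiling = c(41, 1, 1, 1, 1, Inf)
)

#' Generate synthetic six-metric quality profiles
#'
#' Under `model = "latent"`, a per-file badness `b ~ Uniform(0, 1)` drives
#' every metric down monotonically from its best value, plus Gaussian noise
#' scaled by `noise` (at `noise = 0` every metric is a strictly decreasing
#' function of badness). Under `model = "independent"` each metric is drawn
#' independently of the others, so flags carry no shared signal. Optional
#' outliers violate the plausibility bounds (FastQC score above 100 or
#' mapping ratio above 1) and are removed by [cistrome_outlier_filter()].
#'
#' @param n number of profiles
#' @param model `"latent"` or `"independent"`
#' @param noise noise level as a fraction of each metric's span (default
#'   0.1)
#' @param n_outliers number of planted implausible profiles appended
#' @param seed integer seed
#' @return Tibble `file_id`, the six metrics, and (for `"latent"`) the
#'   hidden `badness`.
#' @export
generate_cistrome_profiles <- function(n, model = c("latent", "independent"),
                                       noise = 0.1, n_outliers = 0, seed = 1L) {
  model <- match.arg(model)
  if (n < 1) abort("n must be >= 1")
  with_local_seed(seed, {
    out <- tibble(file_id = sprintf("cp%05d", seq_len(n)))
    if (model == "latent") {
      b <- runif(n)
      out$badness <- b
      for (i in seq_len(nrow(.cistrome_ranges))) {
        r <- .cistrome_ranges[i, ]
        v <- r$best - r$span * b + noise * r$span * rnorm(n)
        out[[r$metric]] <- pmin(pmax(v, r$floor), r$ceiling)
      }
    } else {
      for (i in seq_len(nrow(.cistrome_ranges))) {
        r <- .cistrome_ranges[i, ]
        out[[r$metric]] <- r$best - r$span * runif(n)
      }
    }
    if (n_outliers > 0) {
      extra <- tibble(file_id = sprintf("out%03d", seq_len(n_outliers)))
      if (model == "latent") extra$badness <- NA_real_
      for (i in seq_len(nrow(.cistrome_ranges))) {
        r <- .cistrome_ranges[i, ]
        extra[[r$metric]] <- r$best
      }
      # alternate the two violation modes
      odd <- seq_len(n_outliers) %% 2 == 1
      extra$FASTQC[odd] <- 120
      extra$UniquelyMappedRatio[!odd] <- 1.2
      out <- bind_rows(out, extra)
    }
    out
  })
}

#' Write / read a Cistrome-style metrics table
#'
#' @param profiles tibble with `file_id` and the six metric columns
#' @param path CSV path
#' @return `path` (writer) or the tibble (reader).
#' @export
write_cistrome_csv <- function(profiles, path) {
  readr::write_csv(profiles, path, na = "NA")
  invisible(path)
}

#' @rdname write_cistrome_csv
#' @export
read_cistrome_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE, na = "NA")
  missing <- setdiff(.cistrome_metrics(), names(tab))
  if (length(missing) > 0) {
    abort(paste0("metrics table missing column(s): ", paste(missing, collapse = ", ")))
  }
  as_tibble(tab)
}
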