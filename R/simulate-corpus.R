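# Synthetic corpora: metadata + quality-dependent feature tables with a
# ground-truth ledger, emulating a curated NGS repository at desk scale.
#
# Continuous features are drawn from a latent normal with a class shift of
# d within-class standard deviations (lognormal = exp of the same latent,
# leaving rank statistics untouched), so the analytic orientation-max
# auROC is pnorm(d / sqrt(2)). Ordinal (RAW-style) features discretize the
# same latent at fixed cut points into fail/warning/pass.

#' Describe planted feature effects
#'
#' @param feature feature names to shift
#' @param d effect size in within-class standard deviations (>= 0)
#' @param dist `"normal"`, `"lognormal"` or `"ordinal"` base distribution
#' @param direction `"high-greater"` (high-quality class has larger
#'   values) or `"low-greater"`
#' @return Tibble usable as the `effects` argument of
#'   [generate_corpus()].
#' @export
effect_spec <- function(feature, d, dist = "normal", direction = "high-greater") {
  if (any(d < 0)) abort("effect size d must be >= 0")
  tibble(feature = feature, d = d, dist = dist, direction = direction)
}

# ordinal cut points on the latent scale: ~10% fail, 20% warning, 70% pass
.ordinal_cuts <- qnorm(c(0.1, 0.3))

.draw_feature <- function(n, shift, dist) {
  z <- rnorm(n, mean = shift)
  switch(dist,
    normal = z,
    lognormal = exp(z),
    ordinal = findInterval(z, .ordinal_cuts),
    abort(paste0("unknown base distribution: ", dist))
  )
}

#' Generate a synthetic corpus
#'
#' Builds a labelled corpus from subset blueprints: each blueprint names
#' the defining metadata values of one condition subset, its class sizes,
#' and (optionally) which features carry a planted quality effect. All 47
#' features are emitted with the run-type NA pattern of real data (MAP_PE
#' blocks NA for SE files and vice versa); features without a planted
#' effect are exchangeable between classes. Deterministic per seed.
#'
#' @param blueprints tibble with metadata columns (`organism`, `assay`,
#'   `assay_title`, `run_type`, optionally `biological_sample`,
#'   `target_protein`, `antibody`) and counts `n_high`, `n_low`; one row
#'   per planted subset. An optional list-column `effects` holds an
#'   [effect_spec()] per blueprint.
#' @param effects an [effect_spec()] tibble applied to every blueprint
#'   lacking its own (default: no effects anywhere)
#' @param seed integer seed
#' @return List: `records` (metadata tibble), `features` (feature table),
#'   `truth` (ledger tibble: blueprint row, feature, d, dist, direction
#'   and the analytic `auroc` `pnorm(d/sqrt(2))` for latent-normal
#'   effects).
#' @export
#' @examples
#' bp <- tibble::tibble(
#'   organism = "human", assay = "ChIP-seq", assay_title = "TF ChIP-seq",
#'   run_type = "SE", biological_sample = "K562", n_high = 15, n_low = 15
#' )
#' sim <- generate_corpus(bp, effect_spec("MAP_SE_multiple", d = 2), seed = 1)
generate_corpus <- function(blueprints, effects = NULL, seed = 1L) {
  if (nrow(blueprints) == 0) abort("no blueprints")
  if (!all(c("n_high", "n_low") %in% names(blueprints))) {
    abort("blueprints need n_high and n_low")
  }
  if (any(blueprints$n_high + blueprints$n_low < 2)) {
    abort("each blueprint needs at least 2 files")
  }
  defaults <- list(
    organism = "human", assay = "ChIP-seq", assay_title = "TF ChIP-seq",
    run_type = "SE"
  )
  meta_cols <- c(
    "organism", "assay", "assay_title", "run_type",
    "biological_sample", "target_protein", "antibody"
  )
  with_local_seed(seed, {
    out <- purrr::map(seq_len(nrow(blueprints)), function(b) {
      bp <- blueprints[b, ]
      eff <- if ("effects" %in% names(blueprints) && !is.null(bp$effects[[1]])) {
        bp$effects[[1]]
      } else if (!is.null(effects)) {
        effects
      } else {
        effect_spec(character(0), numeric(0))
      }
      bad_f <- setdiff(eff$feature, feature_names())
      if (length(bad_f) > 0) {
        abort(paste0("effects name unknown feature(s): ", paste(bad_f, collapse = ", ")))
      }
      n_h <- bp$n_high
      n_l <- bp$n_low
      n <- n_h + n_l
      quality <- c(rep("high", n_h), rep("low", n_l))
      rec <- tibble(
        file_id = sprintf("bp%02d_f%03d", b, seq_len(n)),
        quality = quality
      )
      for (col in meta_cols) {
        rec[[col]] <- if (col %in% names(bp) && !is.na(bp[[col]])) {
          bp[[col]]
        } else if (col %in% names(defaults)) {
          defaults[[col]]
        } else {
          NA_character_
        }
      }
      feats <- tibble(file_id = rec$file_id, run_type = rec$run_type)
      for (f in feature_names()) {
        na_block <- if (rec$run_type[[1]] == "SE") "MAP_PE_" else "MAP_SE_"
        if (startsWith(f, na_block)) {
          feats[[f]] <- NA_real_
          next
        }
        i <- match(f, eff$feature)
        dist <- if (startsWith(f, "RAW_")) "ordinal" else "normal"
        d <- 0
        dirn <- "high-greater"
        if (!is.na(i)) {
          d <- eff$d[[i]]
          dist <- eff$dist[[i]]
          dirn <- eff$direction[[i]]
        }
        shift_high <- if (dirn == "high-greater") d else 0
        shift_low <- if (dirn == "high-greater") 0 else d
        feats[[f]] <- c(
          .draw_feature(n_h, shift_high, dist),
          .draw_feature(n_l, shift_low, dist)
        )
      }
      truth <- if (nrow(eff) > 0) {
        mutate(eff,
          blueprint = b,
          auroc = if_else(.data$dist %in% c("normal", "lognormal"),
            pnorm(.data$d / sqrt(2)), NA_real_
          )
        )
      } else {
        tibble(
          feature = character(0), d = numeric(0), dist = character(0),
          direction = character(0), blueprint = integer(0), auroc = numeric(0)
        )
      }
      list(records = rec[, c("file_id", "quality", meta_cols)], features = feats, truth = truth)
    })
    list(
      records = purrr::map_dfr(out, "records"),
      features = purrr::map_dfr(out, "features"),
      truth = purrr::map_dfr(out, "truth")
    )
  })
}
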