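#' Select a cluster number from an ARI stability sweep
#'
#' Given adjusted-Rand-index stability values over an ascending candidate
#' range of cluster numbers, finds the first run of at least `window`
#' consecutive candidates with `ARI > threshold` and, within that run,
#' chooses the k with the highest ARI (ties go to the smallest k). What the
#' ARI compares (replicate seeds, consecutive k, ...) is up to the caller —
#' only the selection rule lives here. The first-round convention uses a
#' window of five; the refinement round on a restricted region uses four
#' (`window = 4`).
#'
#' @param sweep Tibble with strictly increasing `k` and `ari` in `[-1, 1]`.
#' @param threshold ARI stability threshold (default 0.65).
#' @param window Required run length (default 5).
#' @return An `ari_selection` list: `chosen_k`, `range_k` (the qualifying
#'   run's k values), `sweep` (input with `in_run` flag).
#' @export
#' @examples
#' sweep <- tibble::tibble(k = 4:10,
#'                         ari = c(0.5, 0.7, 0.7, 0.8, 0.66, 0.7, 0.4))
#' select_k_by_ari(sweep)$chosen_k # 7
select_k_by_ari <- function(sweep, threshold = 0.65, window = 5) {
  if (!all(c("k", "ari") %in% names(sweep))) {
    rlang::abort("`sweep` must have columns `k` and `ari`.")
  }
  if (nrow(sweep) < window) {
    rlang::abort("Need at least `window` candidate cluster numbers.")
  }
  if (any(diff(sweep$k) <= 0)) {
    rlang::abort("`k` must be strictly increasing.")
  }
  if (any(sweep$ari < -1 | sweep$ari > 1)) {
    rlang::abort("ARI values must lie in [-1, 1].")
  }
  ok <- sweep$ari > threshold
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= window)
  if (length(hit) == 0L) {
    rlang::abort(
      paste0("No run of ", window, " consecutive candidates with ARI > ",
             threshold, "; consider lowering the threshold."),
      class = "plastispot_no_stable_range"
    )
  }
  idx <- starts[hit[1]]:ends[hit[1]]
  run_k <- sweep$k[idx]
  run_ari <- sweep$ari[idx]
  chosen <- run_k[which.max(run_ari)]  # which.max takes the first = smallest k
  structure(
    list(chosen_k = chosen, range_k = run_k,
         sweep = dplyr::mutate(sweep, in_run = dplyr::row_number() %in% idx),
         threshold = threshold, window = window),
    class = "ari_selection"
  )
}

#' @export
print.ari_selection <- function(x, ...) {
  cat("<ari_selection> k =", x$chosen_k, "from stable range",
      min(x$range_k), "-", max(x$range_k), "\n")
  invisible(x)
}

#' Rank sub-domains by regional plasticity
#'
#' The regional plasticity of a sub-domain is the mean per-spot summed
#' plasticity (typically over fibroblast subtypes, from
#' [spot_plasticity()]) across its member spots. Sub-domains are ranked
#' descending (1 = most plastic) and relabeled by rank so labels are
#' comparable across samples and time points; score ties break by original
#' sub-domain id, ascending.
#'
#' @param labels Tibble with `spot_id` and `subdomain`.
#' @param spot_scores Tibble with `spot_id` and `plasticity` (e.g.
#'   `spot_plasticity(...)$by_spot`); every labeled spot must be scored.
#' @return Tibble: `subdomain`, `n_spots`, `regional_plasticity`, `rank`.
#' @export
regional_plasticity <- function(labels, spot_scores) {
  if (!all(c("spot_id", "subdomain") %in% names(labels))) {
    rlang::abort("`labels` must have spot_id and subdomain columns.")
  }
  joined <- dplyr::left_join(labels,
                             dplyr::select(spot_scores, "spot_id",
                                           "plasticity"),
                             by = "spot_id")
  if (anyNA(joined$plasticity)) {
    rlang::abort("Every labeled spot needs a plasticity score.")
  }
  if (is.factor(labels$subdomain)) {
    empty <- setdiff(levels(labels$subdomain),
                     unique(as.character(labels$subdomain)))
    if (length(empty) > 0L) {
      rlang::abort(paste0("Empty sub-domain(s): ",
                          paste(empty, collapse = ", ")))
    }
  }
  out <- joined |>
    dplyr::group_by(subdomain = as.character(.data$subdomain)) |>
    dplyr::summarise(n_spots = dplyr::n(),
                     regional_plasticity = mean(.data$plasticity),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$regional_plasticity), .data$subdomain)
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Filtered cell-type composition of sub-domains
#'
#' For each sub-domain, computes dominant-type fractions, keeps the types
#' contributing at least `min_frac`, and walks them in descending order
#' until the cumulative included fraction first reaches `cum_threshold`
#' (the crossing type is included) or the eligible types run out. The
#' surviving set is the sub-domain's cell-type "neighborhood". With
#' `rule_order = "accumulate_first"` the cumulative cut is applied before
#' the per-type floor instead.
#'
#' @param labels Tibble with `spot_id` and `subdomain`.
#' @param dominant Tibble with `spot_id` and `dominant_type` (e.g.
#'   [assign_dominant()] output).
#' @param cum_threshold Cumulative composition target in `(0, 1]`
#'   (default 0.90).
#' @param min_frac Per-type inclusion floor in `[0, 1)` (default 0.05).
#' @param rule_order `"eligibility_first"` (default) or
#'   `"accumulate_first"`.
#' @return Tibble: `subdomain`, `cell_type`, `fraction`, `included`, sorted
#'   by descending fraction within sub-domain.
#' @export
composition_summary <- function(labels, dominant, cum_threshold = 0.90,
                                min_frac = 0.05,
                                rule_order = c("eligibility_first",
                                               "accumulate_first")) {
  rule_order <- match.arg(rule_order)
  if (!(cum_threshold > 0 && cum_threshold <= 1)) {
    rlang::abort("`cum_threshold` must be in (0, 1].")
  }
  if (!(min_frac >= 0 && min_frac < 1)) {
    rlang::abort("`min_frac` must be in [0, 1).")
  }
  joined <- dplyr::inner_join(labels,
                              dplyr::select(dominant, "spot_id",
                                            "dominant_type"),
                              by = "spot_id")
  if (nrow(joined) < nrow(labels)) {
    rlang::abort("Every labeled spot needs a dominant type.")
  }
  fr <- joined |>
    dplyr::count(subdomain = as.character(.data$subdomain),
                 cell_type = .data$dominant_type) |>
    dplyr::group_by(.data$subdomain) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$fraction), .data$cell_type,
                   .by_group = TRUE)

  include_walk <- function(frac) {
    inc <- logical(length(frac))
    if (rule_order == "eligibility_first") {
      elig <- frac >= min_frac
      cum <- 0
      for (i in which(elig)) {
        inc[i] <- TRUE
        cum <- cum + frac[i]
        if (cum >= cum_threshold) break
      }
    } else {
      cum <- 0
      for (i in seq_along(frac)) {
        inc[i] <- TRUE
        cum <- cum + frac[i]
        if (cum >= cum_threshold) break
      }
      inc <- inc & frac >= min_frac
    }
    inc
  }
  fr <- dplyr::mutate(fr, included = include_walk(.data$fraction))
  dplyr::select(dplyr::ungroup(fr), "subdomain", "cell_type", "fraction",
                "included")
}

#' Condition-level neighbor cell types across time points
#'
#' Within each sample, a cell type is a neighborhood candidate when it
#' appears in the included composition of at least `min_subdomains`
#' sub-domains. A type is called a neighbor for a condition when it is a
#' candidate on at least `min_timepoints` distinct developmental days of
#' that condition.
#'
#' @param compositions Tibble combining [composition_summary()] outputs
#'   across samples, with columns `sample`, `condition`, `day`, `subdomain`,
#'   `cell_type`, `included`.
#' @param min_subdomains Minimum sub-domains per sample (default 2).
#' @param min_timepoints Minimum distinct days per condition (default 2).
#' @return Tibble: `condition`, `cell_type` for each neighbor call, plus a
#'   `n_days` column with the number of qualifying days.
#' @export
neighbor_celltypes <- function(compositions, min_subdomains = 2,
                               min_timepoints = 2) {
  need <- c("sample", "condition", "day", "subdomain", "cell_type",
            "included")
  if (!all(need %in% names(compositions))) {
    rlang::abort(paste0("`compositions` must have columns: ",
                        paste(need, collapse = ", ")))
  }
  universes <- compositions |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(types = list(sort(unique(.data$cell_type))),
                     .groups = "drop")
  if (length(unique(universes$types)) > 1L) {
    rlang::warn("Cell-type universes differ across samples; using the union.")
  }
  candidates <- compositions |>
    dplyr::filter(.data$included) |>
    dplyr::group_by(.data$sample, .data$condition, .data$day,
                    .data$cell_type) |>
    dplyr::summarise(n_subdomains = dplyr::n_distinct(.data$subdomain),
                     .groups = "drop") |>
    dplyr::filter(.data$n_subdomains >= min_subdomains)
  candidates |>
    dplyr::group_by(.data$condition, .data$cell_type) |>
    dplyr::summarise(n_days = dplyr::n_distinct(.data$day),
                     .groups = "drop") |>
    dplyr::filter(.data$n_days >= min_timepoints)
}

#' Two-round recursive sub-domain driver
#'
#' Thin orchestration around a user-supplied clustering callback: round one
#' clusters the whole tissue and the valve domain is taken as the cluster
#' with the highest proportion of valve-type spots; round two re-clusters
#' the valve domain's spots into sub-domains. The clustering itself (model,
#' k selection) is entirely the callback's responsibility.
#'
#' @param spots Tibble with `spot_id` plus whatever the callback needs.
#' @param dominant Tibble with `spot_id`, `dominant_type`.
#' @param cluster_fn Function `(spots, round) -> tibble(spot_id, cluster)`.
#' @param valve_types Character vector of valve cell-type names.
#' @return List: `valve_domain` (chosen round-1 cluster id), `labels`
#'   (tibble: spot_id, subdomain for the valve spots), `round1` (full
#'   round-1 labels).
#' @export
recursive_subdomains <- function(spots, dominant, cluster_fn, valve_types) {
  r1 <- cluster_fn(spots, 1L)
  if (!all(c("spot_id", "cluster") %in% names(r1))) {
    rlang::abort("`cluster_fn` must return columns spot_id and cluster.")
  }
  valve_frac <- r1 |>
    dplyr::left_join(dplyr::select(dominant, "spot_id", "dominant_type"),
                     by = "spot_id") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(frac = mean(.data$dominant_type %in% valve_types),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$frac), .data$cluster)
  valve_domain <- valve_frac$cluster[1]
  valve_spots <- dplyr::semi_join(
    spots, dplyr::filter(r1, .data$cluster == valve_domain), by = "spot_id")
  r2 <- cluster_fn(valve_spots, 2L)
  list(
    valve_domain = valve_domain,
    labels = dplyr::rename(r2, subdomain = "cluster"),
    round1 = r1
  )
}
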