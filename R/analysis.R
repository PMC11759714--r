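## analysis: phase flux statistics, rank correlations with permutation
## inference, DOC excursions, and iron redistribution.

#' Phase statistics of a flux series
#'
#' Sample-weighted mean, maximum and trapezoidal cumulative of a flux series
#' within each phase window of the plan, plus a pooled row over both drain
#' phases (samples from the two drains are pooled with equal weight per
#' sample).  A sample taken at a phase boundary belongs to the phase that
#' ends there.
#'
#' @param flux_series Data frame with `time_days` and a flux column
#'   (`flux_umol_per_s_per_m2`, or the first non-time numeric column).
#' @param plan A phase plan ([phase_plan()]).
#' @return A `phase_stats` tibble: `phase`, `kind`, `n`, `mean`, `max`,
#'   `cumulative` (flux integrated over days).
#' @export
phase_statistics <- function(flux_series, plan) {
  fcol <- if ("flux_umol_per_s_per_m2" %in% names(flux_series)) {
    "flux_umol_per_s_per_m2"
  } else {
    setdiff(names(flux_series)[vapply(flux_series, is.numeric, TRUE)],
            "time_days")[1]
  }
  t <- flux_series$time_days
  v <- flux_series[[fcol]]
  ph <- plan$phases
  if (max(t) < ph$t_start[nrow(ph)] || min(t) > ph$t_end[1]) {
    stop("flux series does not cover the phase plan (series spans ",
         signif(min(t), 3), "-", signif(max(t), 3), " d, plan ends at ",
         max(ph$t_end), " d)", call. = FALSE)
  }
  kind <- phase_of(t, plan)
  one <- function(sel, label, k) {
    if (!any(sel)) {
      return(tibble::tibble(phase = label, kind = k, n = 0L,
                            mean = NA_real_, max = NA_real_,
                            cumulative = NA_real_))
    }
    ts <- t[sel]; vs <- v[sel]
    cumtrap <- if (sum(sel) > 1) {
      sum(diff(ts) * (head(vs, -1) + tail(vs, -1)) / 2)
    } else 0
    tibble::tibble(phase = label, kind = k, n = sum(sel),
                   mean = mean(vs), max = max(vs), cumulative = cumtrap)
  }
  rows <- purrr::map_dfr(seq_len(nrow(ph)), function(i) {
    sel <- if (i == 1) {
      t >= ph$t_start[i] & t <= ph$t_end[i]
    } else {
      t > ph$t_start[i] & t <= ph$t_end[i]
    }
    one(sel, paste0(ph$kind[i], i), ph$kind[i])
  })
  pooled <- one(!is.na(kind) & kind == "drain", "drain_pooled", "drain")
  ## the pooled integral sums the drain phases rather than bridging the
  ## saturation window between them
  pooled$cumulative <- sum(rows$cumulative[rows$kind == "drain"], na.rm = TRUE)
  out <- dplyr::bind_rows(rows, pooled)
  class(out) <- c("phase_stats", class(out))
  out
}

#' Spearman rank correlation with a permutation test
#'
#' Spearman's rho (average ranks for ties) with a two-sided permutation
#' p-value: `p = (1 + #{|rho_perm| >= |rho|}) / (n_perm + 1)`.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation draw.
#' @return List with `rho`, `p_value`, `n`, `n_perm`.
#' @export
rank_correlation <- function(x, y, n_perm = 10000, seed = 1) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("rank correlation undefined for constant input", call. = FALSE)
  }
  rho <- cor(x, y, method = "spearman")
  set.seed(seed)
  rx <- rank(x); ry <- rank(y)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    r <- cor(rx, sample(ry), method = "pearson")
    if (abs(r) >= abs(rho) - 1e-12) exceed <- exceed + 1L
  }
  list(rho = rho, p_value = (1 + exceed) / (n_perm + 1),
       n = length(x), n_perm = n_perm)
}

#' Saturation-phase DOC increase at a depth
#'
#' Last saturation-phase sample minus last pre-saturation sample of the DOC
#' series at the requested Rhizon depth.
#'
#' @param porewater Data frame with `time_days`, `depth_cm`, `doc_mg_L`.
#' @param plan Phase plan.
#' @param depth_cm Rhizon depth (cm).
#' @return The increase (mg/L).
#' @export
doc_increase <- function(porewater, plan, depth_cm) {
  avail <- sort(unique(porewater$depth_cm))
  if (!depth_cm %in% avail) {
    stop("depth ", depth_cm, " cm not present; available depths: ",
         paste(avail, collapse = ", "), " cm", call. = FALSE)
  }
  d <- porewater[porewater$depth_cm == depth_cm, ]
  sat <- plan$phases[plan$phases$kind == "saturate", ][1, ]
  pre <- d[d$time_days <= sat$t_start, ]
  dur <- d[d$time_days > sat$t_start & d$time_days <= sat$t_end, ]
  if (!nrow(pre) || !nrow(dur)) {
    stop("series lacks pre-saturation or saturation samples", call. = FALSE)
  }
  dur$doc_mg_L[which.max(dur$time_days)] -
    pre$doc_mg_L[which.max(pre$time_days)]
}

#' Iron redistribution between pre- and post-experiment extractions
#'
#' Per layer-and-pool difference (post minus pre) of sequential-extraction
#' iron tables, with per-pool totals.
#'
#' @param pre,post Data frames with `layer`, `pool`, `umol_fe_per_g` and
#'   matching keys.
#' @return List: `delta` (tibble `layer`, `pool`, `delta_umol_fe_per_g`) and
#'   `totals` (per-pool sum of deltas).
#' @export
iron_redistribution <- function(pre, post) {
  key_pre <- paste(pre$layer, pre$pool)
  key_post <- paste(post$layer, post$pool)
  if (!setequal(key_pre, key_post) || length(key_pre) != length(key_post)) {
    stop("pre/post tables have mismatched layer/pool keys", call. = FALSE)
  }
  m <- dplyr::inner_join(pre, post, by = c("layer", "pool"),
                         suffix = c("_pre", "_post"))
  delta <- dplyr::transmute(m, layer = .data$layer, pool = .data$pool,
                            delta_umol_fe_per_g =
                              .data$umol_fe_per_g_post - .data$umol_fe_per_g_pre)
  totals <- dplyr::summarise(dplyr::group_by(delta, .data$pool),
                             total_delta = sum(.data$delta_umol_fe_per_g),
                             .groups = "drop")
  list(delta = delta, totals = totals)
}
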