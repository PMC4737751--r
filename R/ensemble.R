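#' RMSD between two models
#'
#' Root-mean-square deviation over all beads, computed in the shared map
#' frame without superposition: models fitted into one map live in a
#' fixed frame, and aligning them first would erase genuine placement
#' differences.
#'
#' @param model_a,model_b [assembly] objects with identical bead rosters.
#' @return RMSD in Å.
#' @export
model_rmsd <- function(model_a, model_b) {
  roster <- function(m) lapply(m$components, function(c) c$beads$resid)
  if (!identical(roster(model_a), roster(model_b)))
    stop_denfit("models have different bead rosters", "denfit_argument_error")
  xa <- bead_coords(model_a)
  xb <- bead_coords(model_b)
  sqrt(mean(rowSums((xa - xb)^2)))
}

ensemble_models <- function(ensemble, which = c("best", "final")) {
  which <- match.arg(which)
  lapply(ensemble$results, function(r) r[[which]])
}

ensemble_energies <- function(ensemble, which = c("best", "final")) {
  which <- match.arg(which)
  key <- paste0(which, "_score")
  vapply(ensemble$results, function(r) r[[key]]$total, 0)
}

#' Select the best-scored models
#'
#' Keeps the `k` models with the best (lowest-energy, i.e. highest) score;
#' ties are broken by seed, ascending. The protocol default is the 100
#' best of 1,000 runs.
#'
#' @param ensemble a `model_ensemble`.
#' @param k number of models to keep.
#' @return The sub-ensemble (class `model_ensemble`) of the top `k`.
#' @export
select_top <- function(ensemble, k = 100) {
  n <- length(ensemble$results)
  if (k < 1 || k > n)
    stop_denfit(sprintf("k must be in 1..%d", n), "denfit_argument_error")
  en <- ensemble_energies(ensemble)
  seeds <- vapply(ensemble$results, function(r) as.numeric(r$seed %||% NA), 0)
  ord <- order(en, seeds)
  keep <- ord[seq_len(k)]
  structure(list(results = ensemble$results[keep],
                 seeds = ensemble$seeds[keep],
                 schedule = ensemble$schedule, params = ensemble$params),
            class = "model_ensemble")
}

#' Cluster models by pairwise RMSD
#'
#' Complete-linkage agglomerative clustering on the pairwise RMSD matrix,
#' cut at `rmsd_threshold`. The default threshold equals the nominal map
#' resolution, since placement differences below the resolution are not
#' distinguishable by the data.
#'
#' @param ensemble a `model_ensemble` (the top-k sub-ensemble, typically).
#' @param rmsd_threshold cut height in Å.
#' @param which use each run's `"best"` or `"final"` model.
#' @return List of clusters, each of class `model_cluster` with `members`
#'   (model indices into the ensemble), `medoid`, `representative` (best
#'   score in cluster) and `passes_filter` (set by [filter_clusters()]).
#' @export
cluster_models <- function(ensemble, rmsd_threshold = 20,
                           which = c("best", "final")) {
  which <- match.arg(which)
  models <- ensemble_models(ensemble, which)
  n <- length(models)
  if (n == 0)
    stop_denfit("empty ensemble", "denfit_argument_error")
  en <- ensemble_energies(ensemble, which)
  if (n == 1) {
    memb <- 1L
  } else {
    rm <- rmsd_matrix(models)
    hc <- stats::hclust(stats::as.dist(rm), method = "complete")
    cut_h <- min(rmsd_threshold, max(hc$height) + 1)
    memb <- stats::cutree(hc, h = cut_h)
  }
  lapply(sort(unique(memb)), function(g) {
    members <- which(memb == g)
    med <- if (length(members) == 1) members else {
      rmg <- rmsd_matrix(models[members])
      members[which.min(rowSums(rmg))]
    }
    structure(list(members = members,
                   medoid = med,
                   representative = members[which.min(en[members])],
                   passes_filter = NA),
              class = "model_cluster")
  })
}

#' Pairwise RMSD matrix of a list of models
#'
#' @param models list of [assembly] objects with a common roster.
#' @return Symmetric matrix of RMSD values (Å).
#' @export
rmsd_matrix <- function(models) {
  n <- length(models)
  xs <- lapply(models, bead_coords)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    v <- sqrt(mean(rowSums((xs[[i]] - xs[[j]])^2)))
    out[i, j] <- v
    out[j, i] <- v
  }
  out
}

#' Exposure specification
#'
#' Residue selections that must remain solvent-exposed in an acceptable
#' model: binding surfaces for known partners that were deliberately left
#' out of the sampling restraints. Exposure is assessed with a bead-level
#' buriedness proxy: a selected bead is buried when more than
#' `buriedness_threshold` beads of *other* components lie within
#' `neighbor_cutoff`.
#'
#' @param selections named list of `list(component =, range =)` entries
#'   (`range = NULL` means the whole component).
#' @param neighbor_cutoff neighbour distance in Å; default 6.
#' @param buriedness_threshold max foreign neighbours for an exposed bead;
#'   default 8.
#' @param required_fraction fraction of selection beads that must be
#'   exposed for the selection to pass; default 0.5.
#' @return An object of class `exposure_spec`.
#' @export
exposure_spec <- function(selections, neighbor_cutoff = 6,
                          buriedness_threshold = 8,
                          required_fraction = 0.5) {
  structure(list(selections = selections,
                 neighbor_cutoff = neighbor_cutoff,
                 buriedness_threshold = buriedness_threshold,
                 required_fraction = required_fraction),
            class = "exposure_spec")
}

#' Solvent-exposure fraction of a residue selection
#'
#' @param model an [assembly].
#' @param selection `list(component =, range =)`.
#' @param neighbor_cutoff,buriedness_threshold see [exposure_spec()].
#' @return Fraction of selected beads with at most
#'   `buriedness_threshold` foreign beads within `neighbor_cutoff`.
#' @export
exposure_fraction <- function(model, selection, neighbor_cutoff = 6,
                              buriedness_threshold = 8) {
  comp <- model$components[[selection$component]]
  if (is.null(comp))
    stop_denfit(paste0("unknown component: ", selection$component),
                "denfit_argument_error")
  idx <- resolve_selector(comp, selection$range)
  sel <- bead_coords(comp)[idx, , drop = FALSE]
  others <- model$components[setdiff(names(model$components),
                                     selection$component)]
  if (length(others) == 0) return(1)
  foreign <- do.call(rbind, lapply(others, bead_coords))
  d <- cdist(sel, foreign)
  buried <- rowSums(d <= neighbor_cutoff)
  mean(buried <= buriedness_threshold)
}

#' Filter clusters by interface exposure
#'
#' A cluster passes when its representative model keeps every named
#' selection exposed at the required fraction. (A strict mode requiring
#' all members to pass is available via `all_members = TRUE`.)
#'
#' @param clusters list of clusters from [cluster_models()].
#' @param ensemble the ensemble the clusters index into.
#' @param spec an [exposure_spec].
#' @param which `"best"` or `"final"` models.
#' @param all_members require every member model to pass, not just the
#'   representative.
#' @return The clusters with `passes_filter` set and per-selection
#'   exposures attached as `exposures`.
#' @export
filter_clusters <- function(clusters, ensemble, spec,
                            which = c("best", "final"),
                            all_members = FALSE) {
  which <- match.arg(which)
  models <- ensemble_models(ensemble, which)
  lapply(clusters, function(cl) {
    eval_idx <- if (all_members) cl$members else cl$representative
    pass <- TRUE
    expo <- list()
    for (i in eval_idx) {
      fr <- vapply(spec$selections, function(sel)
        exposure_fraction(models[[i]], sel, spec$neighbor_cutoff,
                          spec$buriedness_threshold), 0)
      if (i == cl$representative) expo <- as.list(fr)
      if (length(fr) > 0 && any(fr < spec$required_fraction)) pass <- FALSE
    }
    cl$passes_filter <- pass
    cl$exposures <- expo
    cl
  })
}

#' Representative model and map correlation
#'
#' From the passing clusters, selects the best-scored model overall,
#' renders it at the map's nominal resolution and returns its
#' cross-correlation with the target map over the target's envelope mask.
#' When no cluster passes the filter, an empty result (not an error) is
#' returned with diagnostics of the failed selections.
#'
#' @param clusters filtered clusters (from [filter_clusters()]).
#' @param ensemble the ensemble the clusters index into.
#' @param map target [density_map].
#' @param resolution rendering resolution in Å; default 20.
#' @param threshold,threshold_mode envelope contour for the CC mask.
#' @param which `"best"` or `"final"` models.
#' @return List with `model`, `cc`, `cluster`, `model_index`; or, when
#'   nothing passes, `model = NULL` and `diagnostics`.
#' @export
representative_and_cc <- function(clusters, ensemble, map, resolution = 20,
                                  threshold = 0.7,
                                  threshold_mode = "max_fraction",
                                  which = c("best", "final")) {
  which <- match.arg(which)
  passing <- Filter(function(cl) isTRUE(cl$passes_filter), clusters)
  if (length(passing) == 0) {
    return(list(model = NULL, cc = NA_real_,
                diagnostics = lapply(clusters, function(cl)
                  list(members = cl$members, exposures = cl$exposures))))
  }
  models <- ensemble_models(ensemble, which)
  en <- ensemble_energies(ensemble, which)
  reps <- vapply(passing, function(cl) cl$representative, 0L)
  pick <- reps[which.min(en[reps])]
  model <- models[[pick]]
  rendered <- simulate_map(model, resolution, grid = map)
  mask <- threshold_mask(map, threshold, threshold_mode)
  cc <- cross_correlation(rendered, map, mask = mask)
  list(model = model, cc = cc,
       cluster = passing[[which.min(en[reps])]], model_index = pick)
}
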