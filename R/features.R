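#' Summarize one lesion into a per-visit record
#'
#' ROI means of the four pharmacokinetic maps over the voxels with a
#' successful fit, combined with the lesion's texture features and metadata.
#'
#' @param pk A `pk_maps` object from [fit_map()].
#' @param tex A `texture_features` object from [lesion_texture()].
#' @param mask Logical 3D lesion mask, congruent with the maps.
#' @param patient_id Patient identifier.
#' @param visit `"pre"` or `"post"`.
#' @param group `"CR"` or `"PR"`.
#' @return A one-row `data.frame` (class `lesion_record`) with columns
#'   `patient_id`, `visit`, `group`, the four ROI means, the seven texture
#'   features, and `n_voxels` (count of fit_ok voxels used).
#' @export
summarize_lesion <- function(pk, tex, mask, patient_id, visit, group) {
  if (!identical(dim(pk$ktrans), dim(mask))) {
    stop("summarize_lesion: mask and maps are not congruent", call. = FALSE)
  }
  ok <- pk$fit_ok & mask
  n_ok <- sum(ok)
  if (n_ok == 0L) {
    stop("summarize_lesion: lesion ", patient_id, " (", visit,
         ") has no successfully fitted voxels", call. = FALSE)
  }
  rec <- data.frame(
    patient_id = patient_id, visit = visit, group = group,
    ktrans = mean(pk$ktrans[ok], na.rm = TRUE),
    kep = mean(pk$kep[ok], na.rm = TRUE),
    ve = mean(pk$ve[ok], na.rm = TRUE),
    vp = mean(pk$vp[ok], na.rm = TRUE),
    energy = tex$energy, entropy = tex$entropy, inertia = tex$inertia,
    correlation = tex$correlation, cluster_shade = tex$cluster_shade,
    cluster_prominence = tex$cluster_prominence, idm = tex$idm,
    n_voxels = n_ok,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("lesion_record", class(rec))
  rec
}

#' Build the per-patient pre/post/change feature table
#'
#' Pivots per-visit lesion records into one row per patient with
#' `<feature>_pre`, `<feature>_post` and `<feature>_change` columns, where
#' change = post - pre exactly. Patients missing either visit are dropped
#' with a warning listing them.
#'
#' @param records A `data.frame` of stacked [summarize_lesion()] rows (or any
#'   frame with `patient_id`, `visit`, `group` and feature columns).
#' @param features Character vector of feature columns to pivot; defaults to
#'   every numeric column except `n_voxels`.
#' @return A `feature_table` data.frame, one row per patient, with a `group`
#'   column.
#' @export
build_table <- function(records, features = NULL) {
  if (is.null(features)) {
    num <- vapply(records, is.numeric, logical(1))
    features <- setdiff(names(records)[num], "n_voxels")
  }
  ids <- unique(records$patient_id)
  have_both <- vapply(ids, function(id) {
    v <- records$visit[records$patient_id == id]
    all(c("pre", "post") %in% v)
  }, logical(1))
  if (any(!have_both)) {
    warning("build_table: dropping patients missing a visit: ",
            paste(ids[!have_both], collapse = ", "), call. = FALSE)
  }
  ids <- ids[have_both]
  if (length(ids) == 0L) stop("build_table: no complete patients", call. = FALSE)
  rows <- lapply(ids, function(id) {
    pre <- records[records$patient_id == id & records$visit == "pre", ][1, ]
    post <- records[records$patient_id == id & records$visit == "post", ][1, ]
    if (!identical(pre$group, post$group)) {
      stop("build_table: group differs across visits for ", id, call. = FALSE)
    }
    out <- data.frame(patient_id = id, group = pre$group,
                      stringsAsFactors = FALSE)
    for (f in features) {
      out[[paste0(f, "_pre")]] <- pre[[f]]
      out[[paste0(f, "_post")]] <- post[[f]]
      out[[paste0(f, "_change")]] <- post[[f]] - pre[[f]]
    }
    out
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("feature_table", class(tab))
  tab
}

#' Simulate a per-patient feature table at the generator's class moments
#'
#' Lesion-level cohort simulator: draws per-patient ROI-level Ktrans, ve, vp
#' (and derived Kep) plus co-occurrence entropy directly from the
#' class-conditional truncated-normal moments the phantom generator uses, for
#' both visits, without synthesizing images. Pre- and post-visit values are
#' drawn independently (the printed change-score dispersions are consistent
#' with independent visits). This is the fast route for replicate-level
#' statistics; [make_cohort()] plus the image pipeline is the full route.
#'
#' @param n_cr,n_pr Patients per class.
#' @param seed Integer seed.
#' @return A `feature_table` with `ktrans`, `kep`, `ve`, `vp`, `entropy`
#'   pre/post/change columns and a `group` column.
#' @export
simulate_feature_table <- function(n_cr = 16, n_pr = 16, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  classes <- c(rep("CR", n_cr), rep("PR", n_pr))
  recs <- list()
  for (visit in c("pre", "post")) {
    for (cl in c("CR", "PR")) {
      n <- sum(classes == cl)
      mom <- .lesion_moments[[visit]][[cl]]
      ent <- .entropy_moments[[visit]][[cl]]
      ktrans <- .rtnorm_target(n, mom$ktrans[1], mom$ktrans[2], 0.01, 2)
      ve <- .rtnorm_target(n, mom$ve[1], mom$ve[2], 0.02, 0.9)
      vp <- .rtnorm_target(n, mom$vp[1], mom$vp[2], 5e-4, 0.05)
      entropy <- .rtnorm_target(n, ent[1], ent[2], 0, 10)
      recs[[paste(visit, cl)]] <- data.frame(
        patient_id = sprintf("P%03d", which(classes == cl)),
        visit = visit, group = cl,
        ktrans = ktrans, kep = ktrans / ve, ve = ve, vp = vp,
        entropy = entropy, stringsAsFactors = FALSE
      )
    }
  }
  build_table(do.call(rbind, recs),
              features = c("ktrans", "kep", "ve", "vp", "entropy"))
}

#' Read / write a feature table CSV
#'
#' @param table A `feature_table`.
#' @param path File path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("feature_table", class(tab))
  tab
}
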