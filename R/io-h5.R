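#' Write / read parcellated time series as HDF5
#'
#' On-disk layout: one HDF5 group per participant (named
#' `<group>/<participant_id>`), one dataset per parcel
#' (`parcel<k>`, voxels x TRs), with `TR_s` stored as a file attribute
#' dataset. Requires the `rhdf5` package.
#'
#' @param dataset a `sim_dataset` (annotation tables are written as TSV
#'   next to the HDF5 file).
#' @param path output `.h5` path; `<path>.scenes.tsv` and
#'   `<path>.recall.tsv` are written alongside.
#' @return `path`, invisibly.
#' @export
write_parcel_h5 <- function(dataset, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    abort("HDF5 I/O requires the rhdf5 package")
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(dataset$config$TR_s, path, "TR_s")
  for (grp in names(dataset$series)) {
    rhdf5::h5createGroup(path, grp)
    for (pid in names(dataset$series[[grp]])) {
      gname <- paste0(grp, "/", pid)
      rhdf5::h5createGroup(path, gname)
      arr <- dataset$series[[grp]][[pid]]
      for (k in seq_len(dim(arr)[3])) {
        rhdf5::h5write(arr[, , k], path,
                       paste0(gname, "/parcel", k))
      }
    }
  }
  rhdf5::h5closeAll()
  write_scene_table(dataset$scenes, paste0(path, ".scenes.tsv"))
  write_recall_table(dataset$recall, paste0(path, ".recall.tsv"))
  invisible(path)
}

#' @rdname write_parcel_h5
#' @param TR_s repetition time override; default read from the file.
#' @return `read_parcel_h5()` returns a list with `series` (per group, a
#'   named list of voxels x TR x parcels arrays), `scenes`, `recall` and
#'   `config$TR_s`, structurally compatible with [pool_patterns()].
#' @export
read_parcel_h5 <- function(path, TR_s = NULL) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    abort("HDF5 I/O requires the rhdf5 package")
  }
  ls <- rhdf5::h5ls(path)
  TR_s <- TR_s %||% as.numeric(rhdf5::h5read(path, "TR_s"))
  groups <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  series <- list()
  for (grp in groups) {
    pids <- ls$name[ls$group == paste0("/", grp) & ls$otype == "H5I_GROUP"]
    series[[grp]] <- lapply(stats::setNames(pids, pids), function(pid) {
      dsets <- ls$name[ls$group == paste0("/", grp, "/", pid)]
      ks <- sort(as.integer(sub("^parcel", "", dsets)))
      mats <- lapply(ks, function(k) {
        rhdf5::h5read(path, paste0(grp, "/", pid, "/parcel", k))
      })
      arr <- array(NA_real_, dim = c(dim(mats[[1]]), length(ks)),
                   dimnames = list(NULL, NULL, ks))
      for (i in seq_along(mats)) arr[, , i] <- mats[[i]]
      arr
    })
  }
  rhdf5::h5closeAll()
  scenes_path <- paste0(path, ".scenes.tsv")
  recall_path <- paste0(path, ".recall.tsv")
  list(series = series,
       scenes = if (file.exists(scenes_path)) read_scene_table(scenes_path),
       recall = if (file.exists(recall_path)) read_recall_table(recall_path),
       config = list(TR_s = TR_s))
}
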