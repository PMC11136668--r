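## Hierarchical HDF5 store, one group per entry keyed by its PDB ID:
##   /{ENTRY_ID}/{dataset}
## Dataset names carry their axis as a prefix: atoms_* (per-atom), frames_*
## (per-frame), trajectory_* (whole-trajectory) for MD data; molecular_* and
## atomic_* for quantum-chemical data. A key map in the configuration allows
## reading files that use different dataset names for the same quantities.

.h5_datasets_for <- function(record) {
  if (inherits(record, "trajectory_record")) {
    out <- list(trajectory_coordinates = record$coordinates,
                frames_time = record$frame_times)
    for (nm in names(record$frame_properties))
      out[[paste0("frames_", nm)]] <- record$frame_properties[[nm]]
    for (nm in names(record$trajectory_properties))
      out[[paste0("trajectory_", nm)]] <- record$trajectory_properties[[nm]]
    out
  } else if (inherits(record, "qm_record")) {
    out <- list()
    for (nm in names(record$molecular))
      out[[paste0("molecular_", nm)]] <- record$molecular[[nm]]
    for (nm in names(record$atomic)) {
      v <- record$atomic[[nm]]
      if (is.character(v)) v <- as.character(v)
      out[[paste0("atomic_", nm)]] <- v
    }
    out
  } else {
    stop_ligdyn("validation", "cannot store object of class %s",
                paste(class(record), collapse = "/"))
  }
}

#' Write records to a hierarchical HDF5 file
#'
#' Stores [trajectory_record()] and/or [qm_record()] objects under one group
#' per entry (`/{ENTRY_ID}/{dataset}`). Numeric arrays round-trip
#' bit-identically. An existing file is overwritten when `overwrite = TRUE`,
#' otherwise groups are added to it.
#'
#' @param records a single record or list of records with unique `entry_id`s.
#' @param path output `.h5` file.
#' @param overwrite replace an existing file (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_h5 <- function(records, path, overwrite = TRUE) {
  if (inherits(records, c("trajectory_record", "qm_record")))
    records <- list(records)
  ids <- vapply(records, function(r) r$entry_id, character(1))
  if (anyDuplicated(ids))
    stop_ligdyn("validation", "duplicate entry ids: %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (overwrite && file.exists(path)) unlink(path)
  if (!file.exists(path)) rhdf5::h5createFile(path)
  existing <- tryCatch(unique(rhdf5::h5ls(path)$group), error = function(e) character())
  for (r in records) {
    grp <- r$entry_id
    if (!paste0("/", grp) %in% existing)
      rhdf5::h5createGroup(path, grp)
    for (nm in names(ds <- .h5_datasets_for(r)))
      rhdf5::h5write(ds[[nm]], path, paste0(grp, "/", nm))
  }
  invisible(path)
}

#' List entries or datasets stored in an HDF5 file
#'
#' @param path `.h5` file.
#' @param entry_id if given, the dataset names stored for that entry;
#'   otherwise the entry ids.
#' @return character vector.
#' @export
h5_keys <- function(path, entry_id = NULL) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  if (is.null(entry_id))
    return(ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"])
  sel <- ls$group == paste0("/", entry_id)
  if (!any(sel))
    stop_ligdyn("validation", "no entry '%s' in %s (available: %s)",
                entry_id, path,
                paste(ls$name[ls$group == "/"], collapse = ", "))
  ls$name[sel]
}

#' Read one dataset from a hierarchical HDF5 file
#'
#' @param path `.h5` file.
#' @param entry_id entry key (group name).
#' @param property_name dataset name (e.g. `"trajectory_coordinates"`,
#'   `"frames_time"`, `"atoms_adaptability"`, `"molecular_electron_affinity"`).
#'   Translated through `key_map` when supplied, so files using different
#'   dataset names can be read.
#' @param key_map optional named character vector mapping canonical names to
#'   the names used in the file.
#' @return the stored array/vector, bit-identical to what was written.
#' @export
read_h5 <- function(path, entry_id, property_name, key_map = NULL) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  avail <- h5_keys(path, entry_id)
  name <- property_name
  if (!is.null(key_map) && property_name %in% names(key_map))
    name <- unname(key_map[[property_name]])
  if (!name %in% avail)
    stop_ligdyn("validation", "no dataset '%s' for entry '%s' (available: %s)",
                name, entry_id, paste(avail, collapse = ", "))
  rhdf5::h5read(path, paste0(entry_id, "/", name))
}

#' Read a trajectory record back from an HDF5 file
#'
#' Inverse of [write_h5()] for trajectories: reassembles coordinates, frame
#' times and all `frames_*`/`trajectory_*` datasets.
#'
#' @inheritParams read_h5
#' @return a [trajectory_record()].
#' @export
read_trajectory_h5 <- function(path, entry_id, key_map = NULL) {
  keys <- h5_keys(path, entry_id)
  co <- read_h5(path, entry_id, "trajectory_coordinates", key_map)
  ft <- read_h5(path, entry_id, "frames_time", key_map)
  fp <- list(); tp <- list()
  for (k in keys) {
    if (k %in% c("trajectory_coordinates", "frames_time")) next
    if (startsWith(k, "frames_"))
      fp[[sub("^frames_", "", k)]] <- as.numeric(read_h5(path, entry_id, k))
    else if (startsWith(k, "trajectory_"))
      tp[[sub("^trajectory_", "", k)]] <- read_h5(path, entry_id, k)
  }
  trajectory_record(entry_id, co, ft, fp, tp)
}
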