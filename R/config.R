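## Run configuration: a YAML key-value file can override the element
## vocabulary used for one-hot encoding, van der Waals / covalent radii, and
## the HDF5 dataset-name map used to read files with foreign key strings.

#' Read a ligdyn configuration file
#'
#' Loads a YAML file with any of the keys `vocab` (one-hot element
#' vocabulary for [build_graph()]), `h5_key_map` (named map canonical ->
#' stored dataset name for [read_h5()]) and `radii` (named per-element
#' overrides of the van der Waals radii used by [sasa()] - applied by
#' passing the returned object where supported). Missing keys fall back to
#' package defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return list with `vocab`, `h5_key_map`, `radii`.
#' @export
read_config <- function(path = NULL) {
  cfg <- list(vocab = .default_vocab, h5_key_map = NULL, radii = NULL)
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_ligdyn("format", "config file not found: %s", path)
    user <- yaml::read_yaml(path)
    for (nm in intersect(names(user), names(cfg)))
      cfg[[nm]] <- if (nm == "h5_key_map" || nm == "radii")
        unlist(user[[nm]]) else user[[nm]]
  }
  cfg
}
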