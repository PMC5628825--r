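# Plain-file persistence of a trained prior bundle: matrices as
# headerless CSV plus a JSON manifest, so bundles are portable and
# inspectable without R.

write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Save a trained prior bundle to a directory
#'
#' Writes the aligned prior shapes (one PLY each), the shape/landmark
#' dictionaries, profile statistics and patch dictionary as CSV matrices, and
#' a JSON manifest tying them together.
#'
#' @param priors a [train_priors()] bundle.
#' @param dir output directory (created if needed).
#' @export
save_priors <- function(priors, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- priors$dict
  for (i in seq_len(d$k)) {
    s <- corr_shape(matrix(d$D_S[, i], ncol = 3, byrow = TRUE), d$faces,
                    d$family_id)
    write_mesh(s, file.path(dir, sprintf("prior_%03d.ply", i)))
  }
  write_matrix_csv(priors$stats$mu, file.path(dir, "profile_mu.csv"))
  write_matrix_csv(priors$stats$sigma, file.path(dir, "profile_sigma.csv"))
  write_matrix_csv(priors$patch_dict$D, file.path(dir, "patch_atoms.csv"))
  pd <- priors$patch_dict
  manifest <- list(
    n_priors = d$k, n_vertices = d$n,
    landmark_indices0 = d$landmark_indices - 1L,
    family_id = d$family_id,
    profile = list(m_in = priors$stats$m_in, m_out = priors$stats$m_out,
                   step = priors$stats$step,
                   bandwidth = priors$stats$bandwidth, z = priors$stats$z),
    patch = list(patch_shape = pd$patch_shape, sigma_gate = pd$sigma_gate,
                 k1 = pd$k1,
                 frequencies = attr(pd$bank, "frequencies"),
                 orientations = attr(pd$bank, "orientations")),
    config = priors$config[!vapply(priors$config, is.null, TRUE)])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a prior bundle saved by [save_priors()]
#' @param dir bundle directory.
#' @return an `spssm_priors` object.
#' @export
load_priors <- function(dir) {
  mf <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  shapes <- lapply(seq_len(mf$n_priors), function(i)
    read_mesh(file.path(dir, sprintf("prior_%03d.ply", i)),
              family_id = mf$family_id))
  dict <- build_dictionaries(shapes, mf$landmark_indices0 + 1L)
  stats_ <- structure(list(
    mu = read_matrix_csv(file.path(dir, "profile_mu.csv")),
    sigma = read_matrix_csv(file.path(dir, "profile_sigma.csv")),
    m_in = mf$profile$m_in, m_out = mf$profile$m_out,
    step = mf$profile$step, bandwidth = mf$profile$bandwidth,
    z = mf$profile$z), class = "profile_stats")
  bank <- gabor_bank(mf$patch$frequencies, mf$patch$orientations)
  pd <- structure(list(
    D = read_matrix_csv(file.path(dir, "patch_atoms.csv")),
    patch_shape = as.integer(mf$patch$patch_shape), bank = bank,
    sigma_gate = mf$patch$sigma_gate, k1 = mf$patch$k1,
    train_errors = NULL), class = "patch_dictionary")
  cfg <- do.call(spssm_config, mf$config[names(mf$config) %in%
                                           names(spssm_config())])
  structure(list(dict = dict, stats = stats_, patch_dict = pd, gpa = NULL,
                 config = cfg), class = "spssm_priors")
}
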