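# Fixtures are built in code; nothing binary ships with the tests.

# tiny object table from explicit volumes/densities
fix_table <- function(volumes, densities, dataset = "D1") {
  object_table(volume_cm3 = volumes, weight_g = volumes * densities,
               dataset = dataset, provenance = "fixture")
}

# noiseless power-law population d = c * V^gamma on a log grid
fix_powerlaw_table <- function(c0 = 2, gamma = -0.4, n = 20,
                               vrange = c(1, 1000)) {
  V <- exp(seq(log(vrange[1]), log(vrange[2]), length.out = n))
  fix_table(V, c0 * V^gamma)
}

# deterministic complete trial set where every report is `ratio` times the
# smaller object (in large/small terms), both orders represented
fix_trials <- function(ratio = 2, n_per_group = 2, trials_per_cell = 2,
                       sets = c("Blobs", "Cubes"),
                       pairs = c("A:B", "A:C")) {
  grid <- expand.grid(trial = seq_len(trials_per_cell),
                      order = c("S-L", "L-S"), pair = pairs,
                      object_set = sets,
                      subj = seq_len(n_per_group), group = c("EW", "PV"),
                      stringsAsFactors = FALSE)
  grid$subject <- paste0(grid$group, grid$subj)
  grid$report <- ifelse(grid$order == "S-L", 10 * ratio, 10 / ratio)
  grid[, c("subject", "group", "object_set", "pair", "order", "report")]
}

# write a mesh to a temp file and return the path
fix_mesh_file <- function(mesh, ext = "off") {
  path <- tempfile(fileext = paste0(".", ext))
  if (ext == "off") {
    write_mesh_off(mesh, path)
  } else if (ext == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(apply(mesh$vertices, 1, function(v)
      paste("v", paste(v, collapse = " "))), con)
    writeLines(apply(mesh$faces, 1, function(f)
      paste("f", paste(f, collapse = " "))), con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(mesh$vertices)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(mesh$faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
    writeLines(apply(mesh$faces - 1L, 1, function(f)
      paste(c(3, f), collapse = " ")), con)
  }
  path
}
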