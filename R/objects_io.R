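# Environmental object tables: ingestion, unit normalization, density derivation.

#' Compute volume from bounding-box dimensions
#'
#' Survey-style object records usually carry only length, width and height.
#' The bounding-box convention multiplies the three; coarser than a scanned
#' mesh but the only volume available for such rows.
#'
#' @param length,width,height Positive dimensions in cm. Vectorized.
#' @return Volume in cm^3 (`length * width * height`).
#' @examples
#' volume_from_dims(10, 10, 10)  # 1000
#' @export
volume_from_dims <- function(length, width, height) {
  if (any(!is.finite(length)) || any(!is.finite(width)) || any(!is.finite(height)) ||
      any(length <= 0) || any(width <= 0) || any(height <= 0)) {
    stop("all dimensions must be positive and finite", call. = FALSE)
  }
  length * width * height
}

#' Compute density from weight and volume
#'
#' Density is weight over volume (g/cm^3); weight is treated as functionally
#' equivalent to mass throughout (gravity is constant across the objects).
#'
#' @param weight Weight in g. Vectorized.
#' @param volume Volume in cm^3. Must be strictly positive.
#' @return Density in g/cm^3.
#' @export
compute_density <- function(weight, volume) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("volume must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("weight must be positive and finite", call. = FALSE)
  }
  weight / volume
}

# unit multipliers into the canonical cm^3 / g
.volume_unit_factor <- function(unit) {
  switch(unit,
    cm3 = 1, m3 = 1e6, mm3 = 1e-3, L = 1e3, l = 1e3,
    in3 = 2.54^3,
    stop(sprintf("unknown volume unit '%s'", unit), call. = FALSE))
}

.weight_unit_factor <- function(unit) {
  switch(unit,
    g = 1, kg = 1e3, mg = 1e-3, oz = 28.349523125, lb = 453.59237,
    stop(sprintf("unknown weight unit '%s'", unit), call. = FALSE))
}

.length_unit_factor <- function(unit) {
  switch(unit,
    cm = 1, m = 100, mm = 0.1, `in` = 2.54,
    stop(sprintf("unknown length unit '%s'", unit), call. = FALSE))
}

# dataset id -> expected class labels
.dataset_classes <- data.frame(
  dataset = c("D1", "D2", "D3", "D4", "D5"),
  category = c("artificial", "artificial", "artificial", "natural", "artificial"),
  liftable = c(TRUE, TRUE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

#' Schema for reading an object CSV
#'
#' Maps file columns onto the canonical object-table fields. Either a
#' `volume` column or all three of `length`/`width`/`height` must be mapped;
#' `weight` is mandatory. Units declared per file are converted at parse
#' time (volume: cm3, m3, mm3, L, in3; weight: g, kg, mg, oz, lb; length:
#' cm, m, mm, in).
#'
#' @param volume,length,width,height,weight,id,name,dataset,category,liftable
#'   Column names in the source file (`NULL` where absent).
#' @param volume_unit,weight_unit,length_unit Unit declarations for the file.
#' @param default_dataset Dataset label (`"D1"`..`"D5"`) applied when no
#'   dataset column is mapped.
#' @return A list of class `object_schema`.
#' @export
object_schema <- function(volume = NULL, length = NULL, width = NULL,
                          height = NULL, weight = "weight",
                          id = NULL, name = NULL, dataset = NULL,
                          category = NULL, liftable = NULL,
                          volume_unit = "cm3", weight_unit = "g",
                          length_unit = "cm", default_dataset = "D1") {
  if (is.null(volume) && (is.null(length) || is.null(width) || is.null(height))) {
    stop("schema must map a volume column or all of length/width/height",
         call. = FALSE)
  }
  if (is.null(weight)) stop("schema must map a weight column", call. = FALSE)
  structure(list(volume = volume, length = length, width = width,
                 height = height, weight = weight, id = id, name = name,
                 dataset = dataset, category = category, liftable = liftable,
                 volume_unit = volume_unit, weight_unit = weight_unit,
                 length_unit = length_unit, default_dataset = default_dataset),
            class = "object_schema")
}

#' Construct an object table from vectors
#'
#' The canonical in-memory container: a data.frame with one row per physical
#' object and columns `id, name, dataset, category, liftable, volume_cm3,
#' weight_g, density_g_cm3, volume_method`. Density is always (re)derived
#' from weight and volume.
#'
#' @param volume_cm3,weight_g Positive numerics, cm^3 and g.
#' @param id Unique object identifiers (default `obj1..objN`).
#' @param name Human-readable names.
#' @param dataset One of `"D1"`..`"D5"` per row.
#' @param category `"artificial"` or `"natural"`; defaults from the dataset id.
#' @param liftable Logical; defaults from the dataset id.
#' @param volume_method `"ruler_geometry"`, `"box_dims"` or `"mesh_scan"`.
#' @param provenance Free-form source description stored as an attribute.
#' @return A data.frame of class `object_table`.
#' @export
object_table <- function(volume_cm3, weight_g, id = NULL, name = NULL,
                         dataset = "D1", category = NULL, liftable = NULL,
                         volume_method = "box_dims", provenance = "in-memory") {
  n <- length(volume_cm3)
  if (length(weight_g) != n) stop("volume and weight lengths differ", call. = FALSE)
  if (n == 0) stop("empty object table", call. = FALSE)
  if (any(!is.finite(volume_cm3)) || any(volume_cm3 <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  if (any(!is.finite(weight_g)) || any(weight_g <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  dataset <- rep_len(as.character(dataset), n)
  bad <- !dataset %in% .dataset_classes$dataset
  if (any(bad)) stop("dataset labels must be D1..D5", call. = FALSE)
  cls <- .dataset_classes[match(dataset, .dataset_classes$dataset), ]
  if (is.null(category)) category <- cls$category
  if (is.null(liftable)) liftable <- cls$liftable
  category <- rep_len(as.character(category), n)
  liftable <- rep_len(as.logical(liftable), n)
  if (any(category != cls$category) || any(liftable != cls$liftable)) {
    stop("category/liftable labels inconsistent with dataset ids", call. = FALSE)
  }
  if (is.null(id)) id <- paste0("obj", seq_len(n))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("object ids must be unique", call. = FALSE)
  if (is.null(name)) name <- id
  tab <- data.frame(
    id = id, name = as.character(name), dataset = dataset,
    category = category, liftable = liftable,
    volume_cm3 = as.numeric(volume_cm3), weight_g = as.numeric(weight_g),
    density_g_cm3 = compute_density(weight_g, volume_cm3),
    volume_method = rep_len(as.character(volume_method), n),
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("object_table", "data.frame"),
            provenance = provenance)
}

#' Load an object table from a CSV file
#'
#' Reads a header CSV, applies a column schema, converts units, computes
#' volumes from dimensions where no volume column is mapped, and derives
#' densities. Rows with missing or non-positive volume/weight are dropped and
#' reported via a warning; the dropped rows are attached as attribute
#' `"rejected"` with a `reason` column.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param schema An [object_schema()].
#' @return An `object_table` with attribute `provenance` describing the
#'   source file and parse options.
#' @export
load_object_table <- function(path, schema) {
  if (!inherits(schema, "object_schema")) stop("schema must be an object_schema", call. = FALSE)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c(schema$weight,
            if (!is.null(schema$volume)) schema$volume
            else c(schema$length, schema$width, schema$height))
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("schema error: missing column(s) %s in %s",
                 paste(missing_cols, collapse = ", "), path), call. = FALSE)
  }
  n <- nrow(raw)
  get_opt <- function(col, default) {
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep_len(default, n)
  }
  weight <- suppressWarnings(as.numeric(raw[[schema$weight]])) *
    .weight_unit_factor(schema$weight_unit)
  if (!is.null(schema$volume)) {
    volume <- suppressWarnings(as.numeric(raw[[schema$volume]])) *
      .volume_unit_factor(schema$volume_unit)
    method <- "ruler_geometry"
  } else {
    lf <- .length_unit_factor(schema$length_unit)
    L <- suppressWarnings(as.numeric(raw[[schema$length]])) * lf
    W <- suppressWarnings(as.numeric(raw[[schema$width]])) * lf
    H <- suppressWarnings(as.numeric(raw[[schema$height]])) * lf
    volume <- L * W * H
    method <- "box_dims"
  }
  ok <- is.finite(volume) & volume > 0 & is.finite(weight) & weight > 0
  if (!any(ok)) stop("no valid rows after validation", call. = FALSE)
  if (any(!ok)) {
    reason <- ifelse(!is.finite(volume) | volume <= 0, "invalid volume", "invalid weight")
    rejected <- data.frame(row = which(!ok), reason = reason[!ok],
                           stringsAsFactors = FALSE)
    warning(sprintf("%d row(s) rejected while loading %s", nrow(rejected), path),
            call. = FALSE)
  } else rejected <- NULL
  tab <- object_table(
    volume_cm3 = volume[ok], weight_g = weight[ok],
    id = if (!is.null(schema$id)) as.character(raw[[schema$id]])[ok] else NULL,
    name = if (!is.null(schema$name)) as.character(raw[[schema$name]])[ok] else NULL,
    dataset = get_opt(schema$dataset, schema$default_dataset)[ok],
    category = if (!is.null(schema$category)) get_opt(schema$category, NA)[ok] else NULL,
    liftable = if (!is.null(schema$liftable)) as.logical(get_opt(schema$liftable, NA))[ok] else NULL,
    volume_method = method,
    provenance = sprintf("%s [volume_unit=%s, weight_unit=%s]",
                         path, schema$volume_unit, schema$weight_unit)
  )
  attr(tab, "rejected") <- rejected
  tab
}

#' Write an object table to the normalized CSV schema
#'
#' Columns are fixed to
#' `id,name,dataset,category,liftable,volume_cm3,weight_g,density_g_cm3,volume_method`
#' so that [read_object_table()] round-trips exactly.
#'
#' @param table An `object_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_object_table <- function(table, path) {
  stopifnot(inherits(table, "object_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a normalized object CSV written by [write_object_table()]
#'
#' @param path CSV path.
#' @return An `object_table`.
#' @export
read_object_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  object_table(volume_cm3 = raw$volume_cm3, weight_g = raw$weight_g,
               id = raw$id, name = raw$name, dataset = raw$dataset,
               category = raw$category, liftable = raw$liftable,
               volume_method = raw$volume_method, provenance = path)
}

#' Pool several object tables into one
#'
#' Ids are prefixed with the table's name when duplicated across tables.
#'
#' @param ... `object_table`s, optionally named.
#' @return A pooled `object_table`.
#' @export
pool_object_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !inherits(tabs[[1]], "object_table")) {
    tabs <- tabs[[1]]
  }
  stopifnot(length(tabs) >= 1, all(vapply(tabs, inherits, TRUE, "object_table")))
  nm <- names(tabs)
  if (is.null(nm)) nm <- paste0("t", seq_along(tabs))
  dfs <- lapply(tabs, as.data.frame)
  all_ids <- unlist(lapply(dfs, `[[`, "id"))
  if (anyDuplicated(all_ids)) {
    dfs <- Map(function(d, n) { d$id <- paste(n, d$id, sep = ":"); d }, dfs, nm)
  }
  pooled <- do.call(rbind, c(dfs, list(make.row.names = FALSE)))
  object_table(volume_cm3 = pooled$volume_cm3, weight_g = pooled$weight_g,
               id = pooled$id, name = pooled$name, dataset = pooled$dataset,
               category = pooled$category, liftable = pooled$liftable,
               volume_method = pooled$volume_method,
               provenance = paste(vapply(tabs, attr, "", "provenance"),
                                  collapse = " + "))
}

#' Randomly sample a subset of an object table
#'
#' Matched-size random subsetting (e.g. n = 28 from the survey dataset for
#' comparison against an equally sized scanned dataset). The selection seed
#' is caller-supplied; there is no hidden default.
#'
#' @param table An `object_table`.
#' @param n Subset size.
#' @param seed Integer RNG seed.
#' @return An `object_table` of `n` rows.
#' @export
sample_subset <- function(table, n, seed) {
  stopifnot(inherits(table, "object_table"), n >= 1, n <= nrow(table))
  idx <- with_seed(seed, sample.int(nrow(table), n))
  sub <- as.data.frame(table)[idx, , drop = FALSE]
  object_table(volume_cm3 = sub$volume_cm3, weight_g = sub$weight_g,
               id = sub$id, name = sub$name, dataset = sub$dataset,
               category = sub$category, liftable = sub$liftable,
               volume_method = sub$volume_method,
               provenance = sprintf("%s [subset n=%d seed=%d]",
                                    attr(table, "provenance"), n, seed))
}

#' @export
print.object_table <- function(x, ...) {
  cat(sprintf("object_table: %d objects (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$dataset)), table(x$dataset)),
                    collapse = ", ")))
  cat(sprintf("  volume %.3g-%.3g cm^3, density %.3g-%.3g g/cm^3\n",
              min(x$volume_cm3), max(x$volume_cm3),
              min(x$density_g_cm3), max(x$density_g_cm3)))
  invisible(x)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
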