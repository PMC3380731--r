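#' The reference hemisphere benchmark surface
#'
#' The level-2 icosphere (162 vertices, 320 triangles) cut at the `z >= 0`
#' half-space through the sphere's center: the standard open test surface on
#' which all embedding methods are compared.
#'
#' @return a [trimesh3d].
#' @export
reference_hemisphere <- function() {
  cut_halfspace(make_icosphere(2), "z", "+", origin = c(0, 0, 0))
}

#' Benchmark the embedding panel on one surface
#'
#' Runs each requested method on the mesh, scores the resulting map with
#' both fidelity metrics, and reports one row per (method, seed).
#' Deterministic methods (pca, mds, sammon, isomap, sinusoidal) ignore the
#' seeds and run once; stochastic methods (sne, landmark-isomap) run once
#' per seed so their spread is visible.
#'
#' @param methods character vector, a subset of [embedding_methods()].
#' @param mesh the surface to map; defaults to [reference_hemisphere()].
#' @param k neighbor count for the neighbor score.
#' @param seeds integer seeds for the stochastic methods.
#' @param ... extra arguments passed to [embed_map()].
#' @return a tibble with columns `method`, `seed`, `area_score`,
#'   `neighbor_score`, `runtime_s`.
#' @examples
#' run_benchmark(c("pca", "sinusoidal"))
#' @export
run_benchmark <- function(methods = embedding_methods(),
                          mesh = reference_hemisphere(), k = 3,
                          seeds = 0L, ...) {
  unknown <- setdiff(methods, embedding_methods())
  if (length(unknown))
    stop("unknown method(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(embedding_methods(), collapse = ", "),
         call. = FALSE)
  stochastic <- c("sne", "landmark-isomap")
  rows <- list()
  for (m in methods) {
    run_seeds <- if (m %in% stochastic) seeds else NA_integer_
    for (s in run_seeds) {
      t0 <- proc.time()[["elapsed"]]
      emb <- if (is.na(s)) embed_map(mesh, m, ...)
             else embed_map(mesh, m, seed = s, ...)
      dt <- proc.time()[["elapsed"]] - t0
      sc <- score_map(mesh, emb, k = k)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = m, seed = s, area_score = sc$area_score,
        neighbor_score = sc$neighbor_score, runtime_s = dt)
    }
  }
  if (length(rows) == 0)
    return(tibble::tibble(method = character(0), seed = integer(0),
                          area_score = numeric(0),
                          neighbor_score = numeric(0),
                          runtime_s = numeric(0)))
  do.call(rbind, rows)
}

#' Run the full cartography pipeline
#'
#' Wires the stages end to end: load (or build) the surface, bisect it into
#' six half-sections, map the chosen surface with the requested methods,
#' score every map, optionally enrich with structure-derived channels and
#' rasterize, and record every stage parameter in a manifest so that
#' deterministic configurations rerun byte-identically.
#'
#' @param config named list (or path to a `key = value` text file) with
#'   keys: `fixture` (`"hemisphere"`) or `vert` + `face` (MSMS pair);
#'   optional `section` (one of `+x,-x,+y,-y,+z,-z` to map a section
#'   instead of the input), `methods` (comma-separated, default
#'   `"pca,isomap"`), `k`, `seed`, `pdb` (enables the feature stage),
#'   `resolution`.
#' @param out_dir artifact directory to create.
#' @param force overwrite an existing non-empty `out_dir`.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- read_config(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory ", out_dir,
         " exists and is not empty; use force = TRUE", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  mesh <- stage("surface", {
    if (!is.null(config$vert)) read_msms(config$vert, config$face)
    else if (identical(config$fixture, "hemisphere")) reference_hemisphere()
    else stop("config needs either vert/face paths or fixture = hemisphere")
  })

  sections <- stage("section", {
    secs <- bisect_by_planes(mesh)
    dir.create(file.path(out_dir, "sections"), showWarnings = FALSE)
    for (lab in names(secs)) {
      if (n_faces(secs[[lab]]) == 0) next
      safe <- sub("\\+", "p", sub("-", "m", lab))
      write_msms(secs[[lab]],
                 file.path(out_dir, "sections", paste0(safe, ".vert")),
                 file.path(out_dir, "sections", paste0(safe, ".face")))
    }
    secs
  })

  target <- if (!is.null(config$section)) sections[[config$section]] else mesh
  methods <- strsplit(config$methods %||% "pca,isomap", ",")[[1]]
  k <- as.integer(config$k %||% 3)
  seed <- as.integer(config$seed %||% 0)

  maps <- stage("map", {
    dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
    out <- list()
    for (m in methods) {
      emb <- embed_map(target, m, seed = seed)
      write.table(data.frame(vertex_id = seq_len(nrow(emb$coords)),
                             x = emb$coords[, 1], y = emb$coords[, 2]),
                  file.path(out_dir, "maps", paste0(m, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      out[[m]] <- emb
    }
    out
  })

  stage("evaluate", {
    reports <- lapply(maps, function(emb) {
      sc <- score_map(target, emb, k = k)
      sc[c("method", "area_score", "neighbor_score", "k",
           "n_vertices", "n_faces")]
    })
    jsonlite::write_json(unname(reports),
                         file.path(out_dir, "scores.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  if (!is.null(config$pdb)) {
    stage("enrich", {
      structure <- read_pdb(config$pdb)
      fields <- list(coulomb_potential(structure, mesh = target),
                     kd_hydrophobicity(structure, mesh = target),
                     mean_curvature(target))
      dir.create(file.path(out_dir, "rasters"), showWarnings = FALSE)
      res <- as.integer(config$resolution %||% 256)
      img <- rasterize(maps[[1]], fields, resolution = res)
      write_png(img, file.path(out_dir, "rasters",
                               paste0(names(maps)[1], ".png")))
    })
  }

  manifest <- c(sprintf("molcart_version = %s",
                        as.character(utils::packageVersion("molcart"))),
                sprintf("%s = %s", names(config),
                        vapply(config, paste, "", collapse = ",")),
                sprintf("k = %d", k), sprintf("seed = %d", seed),
                sprintf("methods = %s", paste(methods, collapse = ",")))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[[:space:]]*=[[:space:]]*")
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
}
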