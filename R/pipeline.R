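# Stage orchestration: YAML config in, TSV data + JSON manifest out.
# Deterministic under a fixed config + seed; every stage's parameters,
# derived seed and outputs are recorded so any stage can be re-run alone.

.stage_registry <- function() {
  list(
    synth_bundle = list(
      required = character(0),
      allowed = c("n_fibres", "pas_per_fibre", "fibre_radius",
                  "centroid_spacing", "box_z", "beads_per_pa", "n_tail",
                  "jitter"),
      run = function(params, state, outdir, seed) {
        sys <- do.call(gen_pa_bundle, c(params, list(seed = seed)))
        f <- file.path(outdir, "system.gro")
        write_structure(sys$topology, sys$frame, f, "gro")
        state$system <- sys
        list(outputs = f)
      }),
    synth_micelle = list(
      required = c("n_pa", "radius"),
      allowed = c("n_pa", "radius", "beads_per_pa", "n_tail"),
      run = function(params, state, outdir, seed) {
        sys <- do.call(gen_micelle, c(params, list(seed = seed)))
        f <- file.path(outdir, "system.gro")
        write_structure(sys$topology, sys$frame, f, "gro")
        state$system <- sys
        list(outputs = f)
      }),
    census = list(
      required = character(0),
      allowed = c("sel", "cutoff"),
      run = function(params, state, outdir, seed) {
        sys <- .state_system(state, outdir)
        sel <- params$sel %||% "group hydrophobic_tail"
        cutoff <- params$cutoff %||% 6.0
        cl <- cluster_molecules(sys$frame, sys$topology, sel, cutoff)
        rows <- lapply(seq_along(cl$sizes), function(i) {
          cls <- classify_aggregate(cl, i, sys$frame, sys$topology)
          fm <- if (cls$class == "fibre") {
            fibre_metrics(cl, i, sys$frame, sys$topology)
          } else list(linear_density = NA, diameter = NA)
          data.frame(cluster = i, n_agg = cl$sizes[i], class = cls$class,
                     radius = cls$radius, axial_extent = cls$axial_extent,
                     centroid_x = cls$centroid[1], centroid_y = cls$centroid[2],
                     centroid_z = cls$centroid[3],
                     linear_density = fm$linear_density,
                     diameter = fm$diameter)
        })
        df <- do.call(rbind, rows)
        cents <- as.matrix(df[, c("centroid_x", "centroid_y", "centroid_z")])
        spacing <- if (nrow(df) >= 2L) {
          lattice_spacing(cents, sys$frame$box)$mean_spacing
        } else NA
        f <- file.path(outdir, "census.tsv")
        .write_tsv(df, f, c(sel = sel, cutoff = cutoff,
                            mean_spacing = spacing))
        state$census <- df
        state$mean_spacing <- spacing
        list(outputs = f)
      }),
    rdf = list(
      required = c("sel_a", "sel_b", "r_max", "dr"),
      allowed = c("sel_a", "sel_b", "r_max", "dr", "exclude_same_molecule"),
      run = function(params, state, outdir, seed) {
        sys <- .state_system(state, outdir)
        r <- compute_rdf(sys, params$sel_a, params$sel_b, params$r_max,
                         params$dr,
                         params$exclude_same_molecule %||% TRUE)
        f <- file.path(outdir, "rdf.tsv")
        .write_tsv(data.frame(r = r$r, g = r$g, pairs = r$pair_counts), f,
                   c(sel_a = params$sel_a, sel_b = params$sel_b,
                     r_max = params$r_max, dr = params$dr))
        list(outputs = f)
      }),
    order = list(
      required = c("sel", "kind"),
      allowed = c("sel", "kind", "cutoff"),
      run = function(params, state, outdir, seed) {
        sys <- .state_system(state, outdir)
        series <- switch(params$kind,
          q6 = compute_q6(sys, params$sel,
                          list(cutoff = params$cutoff %||% 6.5)),
          q_tet = compute_tetrahedral_order(sys, params$sel),
          t_trans = compute_translational_order(sys, params$sel),
          stop("unknown order parameter kind: ", params$kind))
        f <- file.path(outdir, paste0("order_", params$kind, ".tsv"))
        .write_tsv(data.frame(time = series$times, value = series$values), f,
                   c(kind = params$kind, sel = params$sel))
        list(outputs = f)
      }),
    solvate = list(
      required = character(0),
      allowed = c("overall_density", "inter_fibre_target", "fibre_radius",
                  "exclusion_radius"),
      run = function(params, state, outdir, seed) {
        sys <- .state_system(state, outdir)
        regions <- list()
        if (!is.null(params$inter_fibre_target)) {
          region <- .inter_fibre_from_census(state, params)
          regions <- list(list(region = region,
                               target = params$inter_fibre_target))
          state$inter_fibre_region <- region
        }
        solv <- reinsert_water(
          sys$frame, sys$topology,
          overall_density = params$overall_density %||% 1.0,
          regions = regions,
          exclusion_radius = params$exclusion_radius %||% 2.4,
          seed = seed)
        f <- file.path(outdir, "solvated.gro")
        write_structure(solv$topology, solv$frame, f, "gro")
        state$system <- list(topology = solv$topology, frame = solv$frame)
        list(outputs = f)
      }),
    density_check = list(
      required = character(0),
      allowed = character(0),
      run = function(params, state, outdir, seed) {
        sys <- .state_system(state, outdir)
        rows <- data.frame(
          region = "box", density = measure_region_density(
            sys$frame, sys$topology, NULL, "group water"))
        if (!is.null(state$inter_fibre_region)) {
          rows <- rbind(rows, data.frame(
            region = "inter_fibre", density = measure_region_density(
              sys$frame, sys$topology, state$inter_fibre_region,
              "group water")))
        }
        f <- file.path(outdir, "densities.tsv")
        .write_tsv(rows, f, c(species = "water"))
        state$densities <- rows
        list(outputs = f)
      })
  )
}

.state_system <- function(state, outdir) {
  if (!is.null(state$system)) return(state$system)
  f <- file.path(outdir, "system.gro")
  if (file.exists(f)) return(read_structure(f, "gro"))
  stop("no system available: run a synth stage first")
}

.inter_fibre_from_census <- function(state, params) {
  if (is.null(state$census)) stop("solvate with inter_fibre_target needs a census stage first")
  fib <- state$census[state$census$class == "fibre", , drop = FALSE]
  if (nrow(fib) < 2L) stop("inter_fibre region needs >= 2 fibres")
  region_spec("inter_fibre",
              axis_points = as.matrix(fib[, c("centroid_x", "centroid_y")]),
              fibre_radius = params$fibre_radius %||%
                stats::median(fib$diameter, na.rm = TRUE) / 2)
}

.write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("# %s", paste(names(header), unname(header),
                                     sep = "=", collapse = " ")), con)
  }
  utils::write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Validate a pipeline configuration
#'
#' @param config named list (or YAML path) with `seed` (integer), `outdir`,
#'   and `stages`: a list of `list(name, params)` entries.
#' @return the normalised config, invisibly; errors list every offending
#'   key.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  reg <- .stage_registry()
  problems <- character(0)
  for (key in c("seed", "outdir", "stages")) {
    if (is.null(config[[key]])) problems <- c(problems, paste0("missing '", key, "'"))
  }
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$name)) {
      problems <- c(problems, sprintf("stage %d: missing 'name'", i))
      next
    }
    if (is.null(reg[[st$name]])) {
      problems <- c(problems, sprintf("stage %d: unknown stage '%s'", i, st$name))
      next
    }
    spec <- reg[[st$name]]
    pn <- names(st$params %||% list())
    extra <- setdiff(pn, spec$allowed)
    missing <- setdiff(spec$required, pn)
    if (length(extra)) {
      problems <- c(problems, sprintf("stage %d (%s): unknown parameter(s) %s",
                                      i, st$name, paste(extra, collapse = ", ")))
    }
    if (length(missing)) {
      problems <- c(problems, sprintf("stage %d (%s): missing parameter(s) %s",
                                      i, st$name, paste(missing, collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("config validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(config)
}

#' Run an analysis pipeline
#'
#' Validates the config, executes the stages in order (each with a seed
#' derived deterministically from the global seed and the stage index), and
#' writes a JSON manifest recording parameters, seeds, outputs and the
#' package version. A failing stage halts the run with its name.
#'
#' @param config named list or YAML file path; see [validate_config()].
#' @return the manifest, invisibly (also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  reg <- .stage_registry()
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env()
  manifest <- list(
    package = "hydrafibre",
    version = as.character(utils::packageVersion("hydrafibre")),
    seed = config$seed,
    stages = list())
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    stage_seed <- (config$seed * 1000L + i) %% .Machine$integer.max
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      reg[[st$name]]$run(st$params %||% list(), state, outdir, stage_seed),
      error = function(e) {
        stop("pipeline halted at stage ", i, " ('", st$name, "'): ",
             conditionMessage(e), call. = FALSE)
      })
    manifest$stages[[i]] <- list(
      name = st$name, params = st$params %||% list(), seed = stage_seed,
      outputs = as.list(res$outputs),
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
  }
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest$path <- mf
  invisible(manifest)
}

#' Summarise a pipeline run
#'
#' Aggregates the stage outputs referenced by a manifest into one summary
#' table (cluster census, lattice spacing, region densities, order
#' parameters), written as TSV and JSON next to the manifest.
#'
#' @param manifest manifest list returned by [run_pipeline()] or the path to
#'   a `manifest.json`.
#' @return data.frame of summary quantities, invisibly.
#' @export
report <- function(manifest) {
  if (is.character(manifest)) {
    path <- manifest
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
    manifest$path <- path
  }
  outdir <- dirname(manifest$path %||% stop("manifest has no path"))
  rows <- list()
  add <- function(q, v) rows[[length(rows) + 1L]] <<- data.frame(
    quantity = q, value = v, stringsAsFactors = FALSE)
  outputs <- unlist(lapply(manifest$stages, function(s) unlist(s$outputs)))
  gone <- outputs[!file.exists(outputs)]
  if (length(gone)) {
    stop("missing stage output(s): ", paste(gone, collapse = ", "))
  }
  census_f <- outputs[basename(outputs) == "census.tsv"]
  if (length(census_f)) {
    if (!file.exists(census_f[1])) stop("missing stage output: ", census_f[1])
    cen <- utils::read.table(census_f[1], header = TRUE, sep = "\t",
                             comment.char = "#")
    if (nrow(cen) == 0L) {
      add("no_aggregates", 1)
    } else {
      add("cluster_count", nrow(cen))
      add("mean_n_agg", mean(cen$n_agg))
      add("n_fibres", sum(cen$class == "fibre"))
      hdr <- readLines(census_f[1], n = 1)
      sp <- sub(".*mean_spacing=([0-9.eE+-]+).*", "\\1", hdr)
      if (sp != hdr) add("mean_spacing", as.numeric(sp))
      if (any(cen$class == "fibre")) {
        add("mean_linear_density",
            mean(cen$linear_density[cen$class == "fibre"]))
      }
    }
  }
  dens_f <- outputs[basename(outputs) == "densities.tsv"]
  if (length(dens_f)) {
    if (!file.exists(dens_f[1])) stop("missing stage output: ", dens_f[1])
    dn <- utils::read.table(dens_f[1], header = TRUE, sep = "\t",
                            comment.char = "#")
    for (r in seq_len(nrow(dn))) {
      add(paste0("density_", dn$region[r]), dn$density[r])
    }
  }
  for (f in outputs[grepl("^order_", basename(outputs))]) {
    if (!file.exists(f)) stop("missing stage output: ", f)
    od <- utils::read.table(f, header = TRUE, sep = "\t", comment.char = "#")
    add(sub("\\.tsv$", "", basename(f)), mean(od$value))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(quantity = character(0), value = numeric(0))
  .write_tsv(df, file.path(outdir, "summary.tsv"),
             c(seed = manifest$seed))
  jsonlite::write_json(
    stats::setNames(as.list(df$value), df$quantity),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(df)
}
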