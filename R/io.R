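# Peak-list and solution-stream file formats, run configuration, and the
# simulate -> index -> evaluate pipeline.

.STREAM_VERSION <- "rfindex-stream-1"

#' Write / read per-image peak lists (CSV)
#'
#' Format: comma-separated with header \code{image_id,x_m,y_m,intensity};
#' coordinates in metres relative to the beam centre.  Images are returned
#' in order of first appearance, peaks in file order.
#'
#' @param images List of peak data frames (\code{x_m}, \code{y_m}, optional
#'   \code{intensity}) or \code{synthetic_image} objects.
#' @param path File path.
#' @return \code{write_peaks}: the path, invisibly. \code{read_peaks}: a
#'   named list of peak data frames.
#' @export
write_peaks <- function(images, path) {
  rows <- lapply(seq_along(images), function(i) {
    p <- images[[i]]
    if (inherits(p, "synthetic_image")) p <- p$peaks
    if (nrow(p) == 0)
      return(data.frame(image_id = integer(), x_m = numeric(),
                        y_m = numeric(), intensity = numeric()))
    data.frame(image_id = i, x_m = p$x_m, y_m = p$y_m,
               intensity = if ("intensity" %in% names(p)) p$intensity
                           else NA_real_)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) {
    warning("empty peak file: ", path)
    return(list())
  }
  hdr <- strsplit(lines[1], ",")[[1]]
  need <- c("image_id", "x_m", "y_m")
  if (!all(need %in% hdr))
    stop("malformed peak file header; need columns ",
         paste(need, collapse = ", "))
  if (length(lines) == 1) {
    # header-only file: a single recorded image with no peaks
    return(list("1" = data.frame(x_m = numeric(), y_m = numeric())))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  bad <- which(!is.finite(tab$x_m) | !is.finite(tab$y_m) |
                 is.na(tab$image_id))
  if (length(bad))
    stop("malformed peak row(s) at line(s) ",
         paste(bad[seq_len(min(5, length(bad)))] + 1, collapse = ", "))
  ids <- unique(tab$image_id)
  out <- lapply(ids, function(id) {
    p <- tab[tab$image_id == id, c("x_m", "y_m", "intensity")]
    if (all(is.na(p$intensity))) p$intensity <- NULL
    rownames(p) <- NULL
    p
  })
  names(out) <- as.character(ids)
  out
}

#' Write / read indexing solutions (text stream)
#'
#' A stable, human-readable stream: per image, per solution, the orientation
#' quaternion, the oriented reciprocal basis rows a*, b*, c* (nm^-1), the
#' match count, completeness and seeding-voxel visits, and the matched
#' (peak, hkl, deviation) table.  The reader inverts the writer exactly.
#'
#' @param solutions_per_image List of \code{indexing_solutions} (or plain
#'   lists of solution lists).
#' @param path File path.
#' @return \code{write_solutions}: the path invisibly;
#'   \code{read_solutions}: list (per image) of lists of solutions.
#' @export
write_solutions <- function(solutions_per_image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines(paste0("# ", .STREAM_VERSION), con)
  for (im in seq_along(solutions_per_image)) {
    res <- solutions_per_image[[im]]
    sols <- if (inherits(res, "indexing_solutions")) res$solutions else res
    writeLines(sprintf(">>> image %d", im), con)
    writeLines(sprintf("n_solutions %d", length(sols)), con)
    for (si in seq_along(sols)) {
      s <- sols[[si]]
      writeLines(sprintf("--- solution %d", si), con)
      writeLines(paste("quaternion", paste(num(s$q), collapse = " ")), con)
      bas <- s$basis
      for (r in 1:3)
        writeLines(paste(c("astar", "bstar", "cstar")[r],
                         paste(num(bas[, r]), collapse = " ")), con)
      writeLines(sprintf("n_matched %d", s$n_matched), con)
      writeLines(paste("completeness", num(s$completeness)), con)
      writeLines(paste("visits", num(s$visits)), con)
      m <- s$matched
      writeLines(sprintf("peaks %d", nrow(m)), con)
      if (nrow(m))
        writeLines(sprintf("%d %d %d %d %.17g", m$g_index, m$h, m$k, m$l,
                           m$deviation), con)
    }
  }
  invisible(path)
}

#' @rdname write_solutions
#' @export
read_solutions <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != paste0("# ", .STREAM_VERSION))
    stop("not an rfindex solution stream (version stamp mismatch)")
  i <- 2
  out <- list()
  while (i <= length(lines)) {
    stopifnot(startsWith(lines[i], ">>> image "))
    i <- i + 1
    nsol <- as.integer(sub("n_solutions ", "", lines[i])); i <- i + 1
    sols <- vector("list", nsol)
    for (si in seq_len(nsol)) {
      stopifnot(startsWith(lines[i], "--- solution")); i <- i + 1
      getv <- function(key) {
        stopifnot(startsWith(lines[i], key))
        v <- as.numeric(strsplit(sub(paste0(key, " "), "", lines[i]),
                                 " ")[[1]])
        i <<- i + 1
        v
      }
      q <- getv("quaternion")
      a <- getv("astar"); b <- getv("bstar"); cc <- getv("cstar")
      n_matched <- as.integer(getv("n_matched"))
      completeness <- getv("completeness")
      visits <- getv("visits")
      npk <- as.integer(getv("peaks"))
      m <- if (npk > 0) {
        rows <- do.call(rbind, lapply(lines[i + seq_len(npk) - 1],
                                      function(s) as.numeric(strsplit(s, " ")[[1]])))
        i <- i + npk
        data.frame(g_index = as.integer(rows[, 1]), h = as.integer(rows[, 2]),
                   k = as.integer(rows[, 3]), l = as.integer(rows[, 4]),
                   deviation = rows[, 5])
      } else data.frame(g_index = integer(), h = integer(), k = integer(),
                        l = integer(), deviation = numeric())
      sols[[si]] <- list(q = q, U = quat_to_matrix(q),
                         basis = cbind(a, b, cc), matched = m,
                         n_matched = n_matched, completeness = completeness,
                         visits = visits)
    }
    out[[length(out) + 1]] <- sols
  }
  out
}

#' Write / read ground truth (JSON)
#'
#' @param images List of \code{synthetic_image} objects.
#' @param path File path.
#' @return \code{write_truth}: path invisibly; \code{read_truth}: list per
#'   image with \code{orientations} (quaternion matrix) and
#'   \code{provenance} data frame.
#' @export
write_truth <- function(images, path) {
  payload <- lapply(images, function(img) list(
    orientations = unname(img$orientations),
    provenance = img$provenance))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(length(raw$orientations)), function(i) list(
    orientations = {
      m <- raw$orientations[[i]]
      if (is.null(m) || length(m) == 0) matrix(numeric(), 0, 4)
      else matrix(as.numeric(m), ncol = 4)
    },
    provenance = as.data.frame(raw$provenance[[i]])))
}

#' Read a sectioned key = value configuration file
#'
#' Sections are headed \code{[name]}; values are auto-converted to numbers
#' where possible.  Lines starting with \code{#} are comments.
#'
#' @param path Config file path.
#' @return Nested named list (section -> key -> value).
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  sect <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      sect <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[sect]][[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

# small stable hash (polynomial rolling hash mod a Mersenne prime) for
# config stamping; only needs to be stable and collision-unlikely
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the simulate -> index -> evaluate pipeline
#'
#' Drives a full reproducible run from a configuration: simulates a set of
#' multi-crystal snapshot images for a named scenario, indexes each image,
#' scores the solutions against the ground truth and writes all artifacts
#' (peak CSV, truth JSON, solution stream, report JSON stamped with a
#' config hash).
#'
#' @param config Nested list (see \code{\link{read_config}}) or a config
#'   file path.  Recognized keys: \code{[run] seed, outdir};
#'   \code{[simulate] scenario, n_images, n_crystals} (or \code{lambda});
#'   \code{[index]} optional overrides of any \code{\link{felix_params}}
#'   field; \code{[evaluate] tolerance_deg}.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the \code{accuracy_report}, artifact
#'   paths and the config hash.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  need <- function(sect, key, default = NULL) {
    v <- config[[sect]][[key]]
    if (is.null(v)) {
      if (is.null(default)) stop("config is missing required field [",
                                 sect, "] ", key)
      default
    } else v
  }
  seed <- need("run", "seed", 1)
  outdir <- need("run", "outdir", ".")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  scn <- scenario(need("simulate", "scenario"))
  for (key in intersect(names(config$index), names(scn$params)))
    scn$params[[key]] <- config$index[[key]]
  n_images <- need("simulate", "n_images")
  fams <- generate_families(scn$cell, scn$params$d_min)
  if (!is.null(config$simulate$lambda)) {
    imgs <- poisson_image_ensemble(config$simulate$lambda, n_images, scn,
                                   families = fams)
  } else {
    ncry <- need("simulate", "n_crystals")
    imgs <- lapply(seq_len(n_images), function(i)
      simulate_image(ncry, scn, families = fams))
  }
  peaks_path <- file.path(outdir, "peaks.csv")
  truth_path <- file.path(outdir, "truth.json")
  write_peaks(imgs, peaks_path)
  write_truth(imgs, truth_path)
  if (verbose) message(sprintf("simulated %d image(s)", length(imgs)))

  acc <- frustum_accumulator(scn$params$n_voxels)
  t0 <- proc.time()[["elapsed"]]
  results <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    ti <- proc.time()[["elapsed"]]
    results[[i]] <- index_image(imgs[[i]]$peaks, scn$cell, scn$geom,
                                scn$params, families = fams, acc = acc)
    if (verbose)
      message(sprintf("image %d: %d peak(s) -> %d solution(s) [%.1f s]",
                      i, results[[i]]$n_peaks,
                      length(results[[i]]$solutions),
                      proc.time()[["elapsed"]] - ti))
  }
  sol_path <- file.path(outdir, "solutions.stream")
  write_solutions(results, sol_path)

  tol <- need("evaluate", "tolerance_deg", 1)
  report <- match_to_truth(results, lapply(imgs, function(x) x$orientations),
                           tolerance_deg = tol,
                           laue_ops = laue_operators(scn$cell$laue_class))
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(list(
    config_hash = .config_hash(config),
    seed = seed,
    scenario = scn$name,
    elapsed_s = proc.time()[["elapsed"]] - t0,
    per_image = report$per_image,
    mean_correct = report$mean_correct,
    fraction_correct = report$fraction_correct,
    tolerance_deg = tol), report_path, digits = NA, auto_unbox = TRUE)
  if (verbose) print(report)
  invisible(list(report = report, paths = list(
    peaks = peaks_path, truth = truth_path, solutions = sol_path,
    report = report_path), config_hash = .config_hash(config)))
}
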