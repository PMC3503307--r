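# Batch orchestration: walk an image tree, build job descriptions, process
# them on a local multi-process work queue with an exactly-once contract,
# and collect order-normalized results.

#' Collect segmentation jobs from a directory tree
#'
#' Walks `root_dir` recursively, creating one job description per
#' recognized raster file (`.png`, `.ppm`, `.pgm`) in deterministic
#' lexicographic order. Unreadable files are enqueued with status
#' `"failed"` so they surface in the result table without affecting the
#' rest of the queue.
#'
#' @param root_dir directory to walk
#' @param params named list of analysis parameters applied to every job:
#'   `pixel_size_um` (required), and optionally `threshold`, `se_size`,
#'   `se_shape`, `downsample_factor`, `min_area_px`, `scan_vertical`
#' @param output_dir where per-job outputs go (default `root_dir`)
#' @return list of `job_description` lists (fields: `job_id`, `image_path`,
#'   `output_path`, `params`, `status`)
#' @export
collect_jobs <- function(root_dir, params, output_dir = root_dir) {
  if (!dir.exists(root_dir)) stop("directory does not exist: ", root_dir)
  if (is.null(params$pixel_size_um))
    stop("params$pixel_size_um is required")
  check_pixel_size(params$pixel_size_um)
  files <- sort(list.files(root_dir, pattern = "\\.(png|ppm|pgm)$",
                           recursive = TRUE, full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) {
    warning("no raster images found under ", root_dir)
    return(list())
  }
  lapply(seq_along(files), function(i) {
    readable <- file.access(files[i], 4) == 0
    structure(list(
      job_id = sprintf("job%04d", i),
      image_path = files[i],
      output_path = file.path(
        output_dir,
        paste0(tools::file_path_sans_ext(basename(files[i])), "_result")),
      params = params,
      status = if (readable) "pending" else "failed"),
      class = "job_description")
  })
}

# Process one job: segment + descriptors; errors become a failure record.
process_job <- function(job) {
  base <- data.frame(job_id = job$job_id,
                     image = basename(job$image_path),
                     stringsAsFactors = FALSE)
  if (identical(job$status, "failed"))
    return(cbind(base, failure_row("unreadable input file")))
  res <- tryCatch({
    p <- job$params
    img <- read_raster(job$image_path, p$pixel_size_um)
    map <- segment_section(
      img,
      threshold = p$threshold,
      se_size = p$se_size %||% 7L,
      se_shape = p$se_shape %||% "square",
      downsample_factor = p$downsample_factor %||% 4L,
      min_area_px = p$min_area_px %||% 0)
    d <- compute_descriptors(map, scan_vertical = isTRUE(p$scan_vertical))
    data.frame(status = "done", n_airspaces = d$n_airspaces,
               n_intercepts = d$n_intercepts, Lm_um = d$Lm_um,
               D0_um = d$D0_um, D1_um = d$D1_um, D2_um = d$D2_um,
               error = "", stringsAsFactors = FALSE)
  }, error = function(e) failure_row(conditionMessage(e)))
  cbind(base, res)
}

failure_row <- function(msg) {
  data.frame(status = "failed", n_airspaces = NA_integer_,
             n_intercepts = NA_integer_, Lm_um = NA_real_, D0_um = NA_real_,
             D1_um = NA_real_, D2_um = NA_real_, error = msg,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a job queue with parallel workers
#'
#' Each job is processed exactly once (segmentation then descriptors); a
#' failing job records its error and does not abort the queue. The result
#' table is sorted by `job_id`, so it is identical regardless of the
#' worker count.
#'
#' @param jobs list from [collect_jobs()]
#' @param n_workers number of worker processes (>= 1); forked workers via
#'   the parallel package where available, sequential otherwise
#' @return data.frame with one row per job (`job_id`, `image`, `status`,
#'   descriptor columns, `error`)
#' @export
run_queue <- function(jobs, n_workers = 1L) {
  if (n_workers < 1) stop("n_workers must be >= 1")
  if (!length(jobs)) {
    return(cbind(data.frame(job_id = character(), image = character()),
                 failure_row("x")[0, ]))
  }
  rows <- if (n_workers == 1L ||
              .Platform$OS.type != "unix") {
    lapply(jobs, process_job)
  } else {
    parallel::mclapply(jobs, process_job, mc.cores = n_workers)
  }
  bad <- vapply(rows, function(r) !is.data.frame(r), logical(1))
  for (i in which(bad)) { # a worker crashed outright
    rows[[i]] <- cbind(
      data.frame(job_id = jobs[[i]]$job_id,
                 image = basename(jobs[[i]]$image_path),
                 stringsAsFactors = FALSE),
      failure_row(paste("worker error:",
                        paste(as.character(rows[[i]]), collapse = " "))))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$job_id), ]
  rownames(out) <- NULL
  out
}
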