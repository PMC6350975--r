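# End-to-end orchestration: configuration, the extract -> encode -> cluster
# -> taxonomy (-> survey) pipeline, and report rendering.

#' Pipeline configuration
#'
#' Validates all pipeline parameters. Defaults are the procedure's standard
#' settings: mask thickening 5 px, mouth enlargement 5 px, blur sigma 2,
#' 45 eigenfaces, K swept 5..30 with 10 runs per K, at most 2 SECs.
#'
#' @param images_dir,landmarks_dir Input directories (omit when `faces` is
#'   given to [run_pipeline()] directly).
#' @param out_dir Output directory.
#' @param schema_file Optional landmark schema JSON.
#' @param thicken_px,shave_enlarge_px,shave_sigma Extraction parameters.
#' @param m Number of eigenfaces.
#' @param k_min,k_max,runs_per_k,max_secs Cluster-number selection
#'   parameters.
#' @param seed Master seed: all stage seeds derive from it.
#' @param ethnic_code Taxonomy ethnic letter.
#' @param kinds Feature kinds to process.
#' @param survey Also run the simulated survey per kind.
#' @param n_targets,temperature Survey size and evaluator temperature
#'   (`NULL` = nearest evaluator).
#' @return A validated `facetax_config` list.
#' @export
pipeline_config <- function(images_dir = NULL, landmarks_dir = NULL,
                            out_dir = tempfile("facetax_"), schema_file = NULL,
                            thicken_px = 5, shave_enlarge_px = 5, shave_sigma = 2,
                            m = 45, k_min = 5, k_max = 30, runs_per_k = 10,
                            max_secs = 2, seed = 1, ethnic_code = "W",
                            kinds = c("eye", "nose", "mouth"), survey = FALSE,
                            n_targets = 200, temperature = NULL) {
  bad <- function(msg) ftx_abort(msg, "config_error")
  for (d in c(images_dir, landmarks_dir)) {
    if (!is.null(d) && !dir.exists(d)) bad(paste("no such directory:", d))
  }
  if (!is.null(schema_file) && !file.exists(schema_file)) bad("schema file not found")
  if (thicken_px < 0 || shave_enlarge_px < 0 || shave_sigma < 0) {
    bad("extraction parameters must be nonnegative")
  }
  if (m < 1) bad("m must be >= 1")
  if (k_min < 1 || k_min > k_max) bad("need 1 <= k_min <= k_max")
  if (runs_per_k < 1) bad("runs_per_k must be >= 1")
  if (max_secs < 0) bad("max_secs must be >= 0")
  if (!grepl("^[A-Z]$", ethnic_code)) bad("ethnic_code must be one uppercase letter")
  if (!all(kinds %in% c("eye", "nose", "mouth"))) bad("unknown feature kind")
  structure(list(images_dir = images_dir, landmarks_dir = landmarks_dir,
                 out_dir = out_dir, schema_file = schema_file,
                 thicken_px = thicken_px, shave_enlarge_px = shave_enlarge_px,
                 shave_sigma = shave_sigma, m = m, k_min = k_min, k_max = k_max,
                 runs_per_k = runs_per_k, max_secs = max_secs, seed = seed,
                 ethnic_code = ethnic_code, kinds = kinds, survey = survey,
                 n_targets = n_targets, temperature = temperature),
            class = "facetax_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys are `pipeline_config()` arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) ftx_abort("config file not found", "config_error")
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

kind_letter <- c(eye = "E", nose = "N", mouth = "M")

#' Run the full classification pipeline
#'
#' Extraction, eigenface encoding, K sweep with Dunn's-Index selection,
#' automatic SEC review, taxonomy coding, and (optionally) the simulated
#' survey — per feature kind. Writes, under `config$out_dir`: one taxonomy
#' JSON and coefficient CSV per kind, a per-K report CSV (best Dunn's
#' Index, SEC count, SEC/K), and a run manifest JSON recording all seeds,
#' parameters and stage counts. A failure in any stage aborts with a
#' stage-tagged error and removes partial outputs. Reruns with identical
#' config produce byte-identical outputs.
#'
#' @param config A `facetax_config`.
#' @param faces Optional in-memory faces tibble (as from
#'   [generate_faces()]); otherwise read from the configured directories.
#' @return A list: `taxonomies` (per kind), `models`, `coefficients`,
#'   `reports` (per-K summaries), `surveys` (when requested), `manifest`.
#' @export
run_pipeline <- function(config, faces = NULL) {
  stopifnot(inherits(config, "facetax_config"))
  schema <- if (is.null(config$schema_file)) default_schema() else
    read_schema(config$schema_file)
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (created) unlink(out_dir, recursive = TRUE)
      ftx_abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
                "pipeline_error", parent = e)
    })
  }

  faces <- stage("input", {
    if (is.null(faces)) {
      if (is.null(config$images_dir) || is.null(config$landmarks_dir)) {
        ftx_abort("no faces given and no input directories configured", "config_error")
      }
      read_faces(config$images_dir, config$landmarks_dir, schema)
    } else faces
  })

  features <- stage("extract", extract_features(
    faces, schema, config$thicken_px, config$shave_enlarge_px,
    config$shave_sigma))
  message(sprintf("extracted %d features from %d faces (%d failed)",
                  nrow(features), nrow(faces), attr(features, "n_failed")))

  kind_seeds <- withr::with_seed(config$seed,
                                 sample.int(.Machine$integer.max - 1L,
                                            2L * length(config$kinds)))
  taxonomies <- list(); models <- list(); coefficients <- list()
  reports <- list(); surveys <- list()
  for (i in seq_along(config$kinds)) {
    kind <- config$kinds[i]
    sub <- filter(features, .data$kind == !!kind)
    pairing <- setNames(sub$face_id, sub$feature_id)
    model <- stage(paste0("encode/", kind), fit_eigenmodel(sub, m = config$m))
    coeffs <- stage(paste0("encode/", kind), encode_features(sub, model))
    sweep <- stage(paste0("cluster/", kind), sweep_k(
      coeffs, config$k_min, config$k_max, config$runs_per_k,
      seed = kind_seeds[2L * i - 1L]))
    sol <- stage(paste0("cluster/", kind),
                 select_k(sweep, kind, pairing, config$max_secs))
    rev <- review_secs(sol, sub)
    tax <- build_taxonomy(sol, coeffs, config$ethnic_code, kind_letter[[kind]],
                          review = rev)
    message(sprintf("%s: K = %d selected (Dunn %.3f), %d SEC(s), %d removed, %d clusters kept",
                    kind, sol$k, sol$dunn, length(sol$sec_clusters),
                    nrow(rev$removed_secs), nrow(tax$clusters)))
    report <- summarize_sweep(sweep, kind, pairing) |>
      select("k", "dunn", "dunn_sd", "n_sec", "sec_per_k")
    stage(paste0("write/", kind), {
      write_taxonomy(tax, file.path(out_dir, paste0("taxonomy_", kind, ".json")))
      write_coefficients(coeffs, file.path(out_dir, paste0("coeffs_", kind, ".csv")))
      write.csv(report, file.path(out_dir, paste0("ksweep_", kind, ".csv")),
                row.names = FALSE)
    })
    if (config$survey) {
      ev <- if (is.null(config$temperature)) evaluator_nearest() else
        evaluator_softmax(config$temperature)
      n_eligible <- sum(tax$clusters$size) - nrow(tax$clusters)
      surveys[[kind]] <- stage(paste0("survey/", kind), simulate_survey(
        tax, coeffs, n_targets = min(config$n_targets, n_eligible),
        evaluator = ev, seed = kind_seeds[2L * i]))
      write.csv(as_tibble(surveys[[kind]]),
                file.path(out_dir, paste0("survey_", kind, ".csv")),
                row.names = FALSE)
    }
    taxonomies[[kind]] <- tax; models[[kind]] <- model
    coefficients[[kind]] <- coeffs; reports[[kind]] <- report
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("facetax")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, kind_seeds = kind_seeds,
    parameters = config[c("thicken_px", "shave_enlarge_px", "shave_sigma", "m",
                          "k_min", "k_max", "runs_per_k", "max_secs",
                          "ethnic_code", "kinds")],
    n_faces = nrow(faces), n_features = nrow(features),
    n_failed_faces = attr(features, "n_failed"),
    clusters_kept = lapply(taxonomies, function(t) nrow(t$clusters))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(taxonomies = taxonomies, models = models, coefficients = coefficients,
       reports = reports, surveys = surveys, manifest = manifest)
}

#' Render per-cluster reports for a taxonomy
#'
#' Writes a summary CSV (code, size, percentage, representative id) and one
#' montage PNG per cluster: the members in a grid, the representative first
#' with a bright frame.
#'
#' @param taxonomy A `facetax_taxonomy`.
#' @param features Feature table holding the member images.
#' @param out_dir Output directory.
#' @return Tibble summary (invisibly the same table written to CSV).
#' @export
render_reports <- function(taxonomy, features, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- tidy(taxonomy)
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  for (i in seq_len(nrow(taxonomy$clusters))) {
    cl <- taxonomy$clusters[i, ]
    ids <- c(cl$representative_id[[1]],
             setdiff(cl$member_ids[[1]], cl$representative_id[[1]]))
    tiles <- features$pixels[match(ids, features$feature_id)]
    tiles <- tiles[!vapply(tiles, is.null, TRUE)]
    if (length(tiles) == 0) next
    montage <- tile_images(tiles, highlight_first = TRUE)
    write_face_image(montage, file.path(out_dir, paste0("cluster_", cl$code, ".png")))
  }
  summary
}

# Arrange same-size tiles into a near-square grid with 2-px separators;
# optionally frame the first tile at full intensity.
tile_images <- function(tiles, highlight_first = FALSE, gap = 2) {
  th <- nrow(tiles[[1]]); tw <- ncol(tiles[[1]])
  if (highlight_first) {
    t1 <- tiles[[1]]
    t1[c(1, 2, th - 1, th), ] <- 1
    t1[, c(1, 2, tw - 1, tw)] <- 1
    tiles[[1]] <- t1
  }
  ncols <- ceiling(sqrt(length(tiles)))
  nrows <- ceiling(length(tiles) / ncols)
  canvas <- matrix(0, nrows * th + (nrows - 1) * gap,
                   ncols * tw + (ncols - 1) * gap)
  for (i in seq_along(tiles)) {
    r <- (i - 1) %/% ncols; c <- (i - 1) %% ncols
    canvas[r * (th + gap) + seq_len(th), c * (tw + gap) + seq_len(tw)] <- tiles[[i]]
  }
  canvas
}
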