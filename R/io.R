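#' Write an ERP dataset as TSV + JSON
#'
#' Plain-text container: one TSV per condition (time column plus one column
#' per channel) and a JSON metadata file carrying the sampling rate,
#' peristimulus window, condition labels, stimulus description and, when
#' present, the ground-truth parameter record.
#'
#' @param dataset an `erpdcm_dataset`
#' @param stem output path stem; writes `<stem>_<condition>.tsv` and
#'   `<stem>.json`
#' @return the metadata path, invisibly
#' @export
write_dataset <- function(dataset, stem) {
  for (cond in dataset$conditions) {
    df <- data.frame(time_ms = dataset$times, t(dataset$y[[cond]]))
    names(df) <- c("time_ms", paste0("ch", seq_len(nrow(dataset$y[[cond]]))))
    utils::write.table(df, paste0(stem, "_", cond, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  gt <- dataset$ground_truth
  meta <- list(srate = dataset$srate,
               window = range(dataset$times),
               conditions = dataset$conditions,
               n_channels = nrow(dataset$y[[1]]),
               input = unclass(dataset$input),
               ground_truth = if (!is.null(gt)) list(
                 theta = as.list(gt$theta), noise_var = gt$noise_var,
                 snr = gt$snr, n_trials = gt$n_trials, seed = gt$seed,
                 leadfield = unclass(gt$leadfield),
                 spec_json = jsonlite::fromJSON(write_model_spec(gt$spec),
                                                simplifyVector = FALSE)))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(stem, ".json"))
}

#' Read an ERP dataset written by [write_dataset()]
#'
#' @param stem the path stem used when writing
#' @return an `erpdcm_dataset`
#' @export
read_dataset <- function(stem) {
  meta <- jsonlite::fromJSON(paste0(stem, ".json"), simplifyVector = TRUE)
  y <- list()
  times <- NULL
  for (cond in meta$conditions) {
    df <- utils::read.table(paste0(stem, "_", cond, ".tsv"), sep = "\t",
                            header = TRUE)
    times <- df$time_ms
    y[[cond]] <- t(as.matrix(df[, -1, drop = FALSE]))
    dimnames(y[[cond]]) <- NULL
  }
  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    g <- meta$ground_truth
    spec <- read_model_spec(jsonlite::toJSON(g$spec_json, auto_unbox = TRUE))
    gt <- list(spec = spec, theta = unlist(g$theta),
               leadfield = lead_field(nrow(g$leadfield), ncol(g$leadfield),
                                      L = g$leadfield),
               noise_var = g$noise_var, snr = g$snr,
               n_trials = g$n_trials, seed = g$seed)
  }
  structure(list(y = y, times = times, srate = meta$srate,
                 conditions = meta$conditions,
                 input = do.call(stimulus_input, as.list(meta$input)),
                 ground_truth = gt),
            class = "erpdcm_dataset")
}

#' Write a posterior estimate as JSON
#'
#' @param posterior an `erpdcm_posterior`
#' @param path output file
#' @export
write_posterior <- function(posterior, path) {
  obj <- list(mean = as.list(posterior$mean),
              sd = as.list(stats::setNames(sqrt(diag(posterior$cov)),
                                           names(posterior$mean))),
              lambda = posterior$lambda,
              F_trace = posterior$F_trace,
              iterations = posterior$iterations,
              converged = posterior$converged,
              n_data = posterior$n_data)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
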