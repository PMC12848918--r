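# YAML study configurations.
#
# A config file holds one block per stand with all generative-truth fields;
# chemistry is a nested season -> variable -> [mean, sd] map. The shipped
# defaults can be written out with write_default_config() and edited.

truth_to_list <- function(s) {
  out <- unclass(s)
  chem <- out$chemistry
  out$chemistry <- NULL
  if (!is.null(chem)) {
    out$chemistry <- lapply(split(chem, chem$season), function(d)
      stats::setNames(lapply(seq_len(nrow(d)),
                             function(i) c(d$mean[i], d$sd[i])),
                      d$variable))
  }
  out
}

truth_from_list <- function(lst) {
  chem <- NULL
  if (!is.null(lst$chemistry)) {
    chem <- do.call(rbind, lapply(names(lst$chemistry), function(season) {
      vars <- lst$chemistry[[season]]
      data.frame(season = season, variable = names(vars),
                 mean = vapply(vars, function(v) v[[1]], 0),
                 sd = vapply(vars, function(v) v[[2]], 0))
    }))
    rownames(chem) <- NULL
  }
  lst$chemistry <- NULL
  do.call(stand_truth, c(lst, list(chemistry = chem)))
}

#' Read and write study configurations (YAML)
#'
#' @param path YAML file path.
#' @param config a [study_config()] to serialise.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` / `write_default_config()` return `path`
#'   invisibly.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  stands <- lapply(raw$stands, truth_from_list)
  study_config(stands = stands,
               start_date = raw$start_date %||% "2023-09-01",
               n_collars = raw$n_collars %||% 18L,
               n_plots = raw$n_plots %||% 3L,
               sample_day = raw$sample_day %||% 10L)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(list(
    start_date = format(config$start_date, "%Y-%m-%d"),
    n_collars = config$n_collars, n_plots = config$n_plots,
    sample_day = config$sample_day,
    stands = lapply(config$stands, truth_to_list)), path,
    precision = 17L)  # doubles must round-trip exactly
  invisible(path)
}

#' @rdname read_study_config
#' @export
write_default_config <- function(path) {
  write_study_config(study_config(), path)
}
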