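## WorkData TSV dialect: columns window_index, lambda_from, lambda_to,
## direction {F, B}, delta_u_kcalmol; a header comment carries the
## temperature.

#' Write / read energy-difference samples as TSV
#'
#' @param work a [WorkData-class].
#' @param path TSV file.
#' @return `path` invisibly (write) or a [WorkData-class] (read).
#' @export
writeWorkDataTSV <- function(work, path) {
  stopifnot(is(work, "WorkData"))
  rows <- list()
  addDir <- function(samples, dir) {
    for (i in seq_along(samples)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        window_index = i, lambda_from = work@lambdas[i],
        lambda_to = work@lambdas[i + 1], direction = dir,
        delta_u_kcalmol = samples[[i]])
    }
  }
  addDir(work@forward, "F")
  addDir(work@backward, "B")
  d <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_K=%g", work@temperature), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWorkDataTSV
#' @export
readWorkDataTSV <- function(path) {
  first <- readLines(path, n = 1)
  temp <- 300
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("temperature_K=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) temp <- as.numeric(m[2])
  }
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  lam <- sort(unique(c(d$lambda_from, d$lambda_to)))
  nTrans <- length(lam) - 1
  grab <- function(dir) {
    sub <- d[d$direction == dir, ]
    if (!nrow(sub)) return(list())
    lapply(seq_len(nTrans), function(i)
      sub$delta_u_kcalmol[sub$window_index == i])
  }
  new("WorkData", forward = grab("F"), backward = grab("B"),
      lambdas = lam, temperature = temp)
}
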