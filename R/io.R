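#' Read a coordinate file into a trajectory
#'
#' Supports fixed-width PDB (`MODEL`/`ENDMDL` multi-frame, `CRYST1` box) and
#' multi-frame XYZ (count / comment / atom lines, frames concatenated). XYZ
#' comment lines may carry `key=value` directives; `box=a,b,c` sets the box
#' and `time=t` the frame time (ps). Without directives the residue metadata
#' of XYZ atoms defaults to residue 1, name `"UNK"`.
#'
#' @param path File path.
#' @param format `"auto"`, `"pdb"` or `"xyz"`.
#' @param box Fallback box (A) when the file carries none.
#' @return A [as_trajectory()] tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz"),
                           box = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (format == "pdb") read_pdb(path, box = box) else read_xyz(path, box = box)
}

read_pdb <- function(path, box = NULL) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  box_line <- which(trimws(rec) == "CRYST1")
  if (length(box_line) > 0) {
    ln <- lines[box_line[1]]
    box <- c(pdb_num(ln, 7, 15, box_line[1]),
             pdb_num(ln, 16, 24, box_line[1]),
             pdb_num(ln, 25, 33, box_line[1]))
  }
  if (is.null(box)) box <- c(100, 100, 100)
  model_starts <- which(trimws(rec) == "MODEL")
  atom_line <- trimws(rec) %in% c("ATOM", "HETATM")
  if (!any(atom_line)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  if (length(model_starts) == 0) {
    frame_of <- ifelse(atom_line, 1L, NA_integer_)
  } else {
    frame_idx <- findInterval(seq_along(lines), model_starts)
    frame_of <- ifelse(atom_line & frame_idx > 0, frame_idx, NA_integer_)
    if (any(atom_line & frame_idx == 0)) {
      stop("ATOM record before first MODEL at line ",
           which(atom_line & frame_idx == 0)[1], call. = FALSE)
    }
  }
  keep <- which(!is.na(frame_of))
  counts <- table(frame_of[keep])
  if (length(unique(as.integer(counts))) > 1) {
    stop("inconsistent atom count across MODEL frames (structure error): ",
         paste(as.integer(counts), collapse = ", "), call. = FALSE)
  }
  ln <- lines[keep]
  n_per <- as.integer(counts[1])
  tbl <- tibble::tibble(
    frame = frame_of[keep],
    atom_id = rep(seq_len(n_per), times = length(counts)),
    atom_name = trimws(substr(ln, 13, 16)),
    residue_name = trimws(substr(ln, 18, 21)),
    chain = trimws(substr(ln, 22, 22)),
    residue_id = pdb_int(ln, 23, 26, keep),
    x = pdb_num(ln, 31, 38, keep),
    y = pdb_num(ln, 39, 46, keep),
    z = pdb_num(ln, 47, 54, keep)
  )
  elem <- trimws(substr(ln, 77, 78))
  tbl$element <- ifelse(nzchar(elem),
                        paste0(substr(elem, 1, 1),
                               tolower(substr(elem, 2, 2))),
                        guess_element(tbl$atom_name))
  tbl$chain[!nzchar(tbl$chain)] <- "A"
  tbl$time <- as.numeric(tbl$frame - 1)
  as_trajectory(tbl, box = box)
}

pdb_num <- function(lines, from, to, line_no) {
  txt <- trimws(substr(lines, from, to))
  val <- suppressWarnings(as.numeric(txt))
  if (any(is.na(val))) {
    i <- which(is.na(val))[1]
    stop("parse error in PDB at line ", line_no[i], ": cannot read '",
         txt[i], "' in columns ", from, "-", to, call. = FALSE)
  }
  val
}

pdb_int <- function(lines, from, to, line_no) {
  v <- pdb_num(lines, from, to, line_no)
  as.integer(v)
}

read_xyz <- function(path, box = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) < length(lines)]
  i <- 1L
  frames <- list()
  frame_no <- 0L
  times <- numeric(0)
  file_box <- NULL
  res_ids <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) {
      stop("parse error in XYZ at line ", i, ": expected atom count, got '",
           trimws(lines[i]), "'", call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop("truncated XYZ frame starting at line ", i, call. = FALSE)
    }
    comment <- lines[i + 1L]
    directives <- xyz_directives(comment)
    if (!is.null(directives$box)) file_box <- directives$box
    frame_no <- frame_no + 1L
    times[frame_no] <- if (!is.null(directives$time)) directives$time else
      frame_no - 1
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    nt <- lengths(toks)
    if (any(nt < 4)) {
      bad <- which(nt < 4)[1]
      stop("parse error in XYZ at line ", i + 1L + bad,
           ": expected 'element x y z'", call. = FALSE)
    }
    el <- vapply(toks, `[[`, character(1), 1)
    xyz <- vapply(toks, function(t) {
      v <- suppressWarnings(as.numeric(t[2:4]))
      v
    }, numeric(3))
    if (any(is.na(xyz))) {
      bad <- which(apply(is.na(xyz), 2, any))[1]
      stop("parse error in XYZ at line ", i + 1L + bad,
           ": non-numeric coordinate", call. = FALSE)
    }
    frames[[frame_no]] <- tibble::tibble(
      frame = frame_no, atom_id = seq_len(n), atom_name = el, element = el,
      x = xyz[1, ], y = xyz[2, ], z = xyz[3, ])
    if (frame_no > 1 && n != nrow(frames[[1]])) {
      stop("inconsistent atom count across XYZ frames (structure error): ",
           nrow(frames[[1]]), " vs ", n, " at line ", i, call. = FALSE)
    }
    i <- i + 2L + n
  }
  tbl <- dplyr::bind_rows(frames)
  tbl$time <- times[tbl$frame]
  tbl$residue_name <- "UNK"
  tbl$residue_id <- 1L
  tbl$chain <- "A"
  if (is.null(box)) box <- if (!is.null(file_box)) file_box else c(100, 100, 100)
  as_trajectory(tbl, box = box)
}

xyz_directives <- function(comment) {
  out <- list()
  toks <- regmatches(comment,
                     gregexpr("[A-Za-z_]+=[-0-9.,eE+]+", comment))[[1]]
  for (t in toks) {
    kv <- strsplit(t, "=")[[1]]
    val <- suppressWarnings(as.numeric(strsplit(kv[2], ",")[[1]]))
    if (identical(tolower(kv[1]), "box") && length(val) == 3) out$box <- val
    if (identical(tolower(kv[1]), "time") && length(val) == 1) out$time <- val
  }
  out
}

#' Write a trajectory to PDB or XYZ
#'
#' PDB output is fixed-width (coordinates to 0.001 A); XYZ output keeps full
#' precision and stores `box=`/`time=` directives on the comment line.
#'
#' @param traj A trajectory.
#' @param path Output path.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(traj, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  box <- traj_box(traj)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      box[1], box[2], box[3], 90, 90, 90), con)
    for (f in sort(unique(traj$frame))) {
      sub <- traj[traj$frame == f, ]
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf(
        "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        (seq_len(nrow(sub)) - 1L) %% 99999L + 1L,
        substr(sub$atom_name, 1, 4), substr(sub$residue_name, 1, 4),
        substr(sub$chain, 1, 1), sub$residue_id %% 10000L,
        sub$x, sub$y, sub$z, toupper(substr(sub$element, 1, 2))), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (f in sort(unique(traj$frame))) {
      sub <- traj[traj$frame == f, ]
      writeLines(as.character(nrow(sub)), con)
      writeLines(sprintf("box=%.6f,%.6f,%.6f time=%.9g",
                         box[1], box[2], box[3], sub$time[1]), con)
      writeLines(sprintf("%s %.9f %.9f %.9f",
                         sub$element, sub$x, sub$y, sub$z), con)
    }
  }
  invisible(path)
}

#' Read a two-column time series
#'
#' Whitespace-delimited `time value` rows; `#` comment lines are ignored.
#' Times must be strictly increasing.
#'
#' @param path File path.
#' @param name Series name (defaults to the file name).
#' @return Tibble with columns `time` (ps) and `value`, plus a `name`
#'   attribute.
#' @export
read_timeseries <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "\\s+")
  if (any(lengths(toks) < 2)) {
    stop("parse error: expected two columns in ", path, call. = FALSE)
  }
  tv <- suppressWarnings(vapply(toks, function(t) as.numeric(t[1:2]),
                                numeric(2)))
  if (any(is.na(tv))) {
    stop("parse error: non-numeric token in ", path, " (row ",
         which(apply(is.na(tv), 2, any))[1], ")", call. = FALSE)
  }
  ts <- tibble::tibble(time = tv[1, ], value = tv[2, ])
  if (any(diff(ts$time) <= 0)) {
    stop("ordering error: times not strictly increasing in ", path,
         call. = FALSE)
  }
  attr(ts, "name") <- name
  ts
}

#' @rdname read_timeseries
#' @param ts Tibble with `time` and `value` columns.
#' @export
write_timeseries <- function(ts, path) {
  nm <- attr(ts, "name")
  header <- sprintf("# %s", if (is.null(nm)) "time value" else nm)
  writeLines(c(header, sprintf("%.9g %.12g", ts$time, ts$value)), path)
  invisible(path)
}

#' Read a WHAM-style umbrella metadata file
#'
#' One entry per line: `data_path bias_center force_constant`, with the
#' force constant in kcal mol^-1 A^-2. Paths are resolved relative to the
#' metadata file's directory. Referenced files are not opened here; a
#' missing file raises an error at [load_umbrella_windows()] time, naming
#' the entry.
#'
#' @param path Metadata file path.
#' @return Tibble with columns `data_path`, `bias_center`, `force_constant`.
#' @export
read_umbrella_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "\\s+")
  if (any(lengths(toks) < 3)) {
    stop("parse error: expected 'path center force_constant' in ", path,
         call. = FALSE)
  }
  meta <- tibble::tibble(
    data_path = vapply(toks, `[[`, character(1), 1),
    bias_center = as.numeric(vapply(toks, `[[`, character(1), 2)),
    force_constant = as.numeric(vapply(toks, `[[`, character(1), 3))
  )
  if (any(is.na(meta$bias_center)) || any(is.na(meta$force_constant))) {
    stop("parse error: non-numeric center/force constant in ", path,
         call. = FALSE)
  }
  if (any(meta$force_constant <= 0)) {
    stop("validation error: force_constant must be > 0 (entry ",
         which(meta$force_constant <= 0)[1], ")", call. = FALSE)
  }
  if (anyDuplicated(meta$data_path)) {
    stop("validation error: duplicate data_path '",
         meta$data_path[duplicated(meta$data_path)][1], "'", call. = FALSE)
  }
  attr(meta, "dir") <- dirname(path)
  meta
}

#' Load the window series referenced by an umbrella metadata table
#'
#' @param meta Result of [read_umbrella_metadata()].
#' @param discard_fraction Initial fraction of each series dropped as
#'   equilibration (the production convention is 0.2, i.e. 2.5 of 12.5 ps).
#' @return List of [umbrella_window()] objects.
#' @export
load_umbrella_windows <- function(meta, discard_fraction = 0.2) {
  dir <- attr(meta, "dir")
  purrr::pmap(meta, function(data_path, bias_center, force_constant) {
    p <- if (file.exists(data_path)) data_path else file.path(dir, data_path)
    if (!file.exists(p)) {
      stop("I/O error: window data file missing for entry '", data_path,
           "'", call. = FALSE)
    }
    ts <- read_timeseries(p)
    umbrella_window(ts$value, bias_center, force_constant,
                    discard_fraction = discard_fraction, times = ts$time)
  })
}
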