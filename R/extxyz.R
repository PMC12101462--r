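#' Read an extended-XYZ file
#'
#' Parses the extended-XYZ dialect: frame header `Lattice="ax ay az bx
#' ..."` (row lattice vectors) and a `Properties=` descriptor naming the
#' per-atom columns.  Frames without a `Lattice` key become gas-phase
#' configurations.  Unrecognised `key=value` comment fields are kept in
#' `info`.  Numbers are written back by [write_extxyz] with 17 significant
#' digits, so a write/read cycle is lossless for doubles.
#'
#' @param path path to the file.
#' @return a list of [atoms] objects, in file order.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  lineno <- function() i
  while (i <= length(lines)) {
    if (!grepl("^\\s*[0-9]+\\s*$", lines[i]))
      stop("extxyz parse error at line ", i, ": expected atom count, got '",
           lines[i], "'")
    nat <- as.integer(trimws(lines[i]))
    if (i + 1L > length(lines))
      stop("extxyz parse error: missing comment line after line ", i)
    header <- lines[i + 1L]
    if (i + 1L + nat > length(lines))
      stop("extxyz structural error: frame starting at line ", i,
           " declares ", nat, " atoms but file ends early")
    body <- lines[(i + 2L):(i + 1L + nat)]
    frames[[length(frames) + 1L]] <- parse_extxyz_frame(nat, header, body, i)
    i <- i + 2L + nat
  }
  frames
}

# split an extxyz comment line into key=value tokens honouring quotes
split_extxyz_header <- function(header) {
  toks <- regmatches(header,
    gregexpr('[A-Za-z_][A-Za-z0-9_]*=(?:"[^"]*"|\\S+)', header))[[1]]
  if (length(toks) == 0) return(list())
  keys <- sub("=.*$", "", toks)
  vals <- sub("^[^=]*=", "", toks)
  vals <- gsub('^"|"$', "", vals)
  stats::setNames(as.list(vals), keys)
}

parse_extxyz_frame <- function(nat, header, body, at_line) {
  kv <- split_extxyz_header(header)
  cell <- NULL
  if (!is.null(kv$Lattice)) {
    v <- as.numeric(strsplit(trimws(kv$Lattice), "\\s+")[[1]])
    if (length(v) != 9 || anyNA(v))
      stop("extxyz parse error at line ", at_line + 1L,
           ": Lattice must hold 9 numbers")
    cell <- matrix(v, 3, 3, byrow = TRUE)
  }
  props <- kv$Properties
  if (is.null(props)) props <- "species:S:1:pos:R:3"
  pf <- strsplit(props, ":")[[1]]
  if (length(pf) %% 3 != 0)
    stop("extxyz parse error at line ", at_line + 1L,
         ": malformed Properties descriptor '", props, "'")
  pnames <- pf[seq(1, length(pf), 3)]
  pcounts <- as.integer(pf[seq(3, length(pf), 3)])
  fields <- strsplit(trimws(body), "\\s+")
  ncol_exp <- sum(pcounts)
  bad <- which(lengths(fields) != ncol_exp)
  if (length(bad))
    stop("extxyz structural error at line ", at_line + 1L + bad[1],
         ": expected ", ncol_exp, " columns")
  tab <- do.call(rbind, fields)
  col <- 1L
  species <- NULL; pos <- NULL; masses <- NULL
  for (k in seq_along(pnames)) {
    idx <- col:(col + pcounts[k] - 1L)
    if (pnames[k] == "species") species <- tab[, idx]
    else if (pnames[k] == "pos")
      pos <- matrix(as.numeric(tab[, idx]), nat, 3)
    else if (pnames[k] %in% c("masses", "mass"))
      masses <- as.numeric(tab[, idx])
    col <- col + pcounts[k]
  }
  if (is.null(species) || is.null(pos))
    stop("extxyz parse error: Properties must include species and pos")
  info <- kv[setdiff(names(kv), c("Lattice", "Properties"))]
  atoms(species = species, positions = pos, cell = cell,
        masses = masses, info = info)
}

#' Write configurations to an extended-XYZ file
#'
#' @param configs an [atoms] object or a list of them.
#' @param path output path.
#' @param extra_fields named character/numeric list written as `key=value`
#'   comment fields on every frame (frame `info` fields are written too).
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(configs, path, extra_fields = list()) {
  if (inherits(configs, "atoms")) configs <- list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) formatC(x, format = "g", digits = 17)
  for (cfg in configs) {
    n <- n_atoms(cfg)
    fields <- character()
    if (cfg$pbc)
      fields <- c(fields, sprintf('Lattice="%s"',
                  paste(num(as.vector(t(cfg$cell))), collapse = " ")))
    fields <- c(fields, "Properties=species:S:1:pos:R:3:masses:R:1")
    info <- c(cfg$info, extra_fields)
    info <- info[vapply(info, function(v)
      is.character(v) || is.numeric(v) || is.logical(v), TRUE)]
    for (k in names(info)) {
      v <- info[[k]]
      v <- if (is.numeric(v)) paste(num(v), collapse = " ") else
        paste(as.character(v), collapse = " ")
      fields <- c(fields, if (grepl("\\s", v))
        sprintf('%s="%s"', k, v) else sprintf("%s=%s", k, v))
    }
    writeLines(as.character(n), con)
    writeLines(paste(fields, collapse = " "), con)
    writeLines(sprintf("%-3s %s %s %s %s", cfg$species,
                       num(cfg$positions[, 1]), num(cfg$positions[, 2]),
                       num(cfg$positions[, 3]), num(cfg$masses)), con)
  }
  invisible(path)
}
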