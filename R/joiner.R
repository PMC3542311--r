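# all.joiner schema parsing and table association.
#
# Supported grammar:
#   # comment lines
#   set <name> <value>
#   identifier <name>
#     "optional description"
#     <db>.<table>.<field> [option tokens...]
# $name substitution is applied at association-definition time (after any
# variable overwrites), and a db component that expands to a comma-separated
# list (the all.joiner `gbd` convention) fans out to one member per
# database. Exceptional directives (chopBefore/chopAfter, splitPrefix,
# exclude, dupeOk, ...) are retained as inert option tokens.

#' Load a joiner schema
#'
#' Parses all.joiner-format text describing which database.table.field
#' members across databases share an identifier namespace and can therefore
#' be joined. `source` is a file path or literal text (anything containing
#' a newline is treated as text). Member lines are stored unexpanded;
#' variable substitution happens when associations are defined, so
#' variables may be overwritten after loading with [joiner_set()].
#'
#' @param source Path to a joiner file, or the schema text itself.
#' @return An object of class `joiner_schema` with fields `variables`
#'   (named list) and `stanzas`.
#' @seealso [define_association()], [joiner_set()]
#' @export
load_joiner <- function(source) {
  if (!is_scalar_string(source)) stop_user("joiner source must be a string")
  lines <- if (grepl("\n", source, fixed = TRUE)) {
    strsplit(source, "\n", fixed = TRUE)[[1L]]
  } else if (file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    source  # single-line literal text
  }
  variables <- list()
  stanzas <- list()
  current <- NULL
  flush <- function() {
    if (!is.null(current)) stanzas[[length(stanzas) + 1L]] <<- current
    current <<- NULL
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^\\s*(#|$)", line)) next
    if (grepl("^set\\s+", line)) {
      m <- regmatches(line, regexec("^set\\s+(\\S+)\\s+(.*\\S)\\s*$", line))[[1L]]
      if (length(m) != 3L) stop_user("line %d: malformed set directive", ln)
      variables[[m[2L]]] <- m[3L]
      next
    }
    if (grepl("^identifier\\s+", line)) {
      flush()
      m <- regmatches(line, regexec("^identifier\\s+(\\S+)", line))[[1L]]
      current <- list(name = m[2L], description = NA_character_, members = list())
      next
    }
    if (grepl("^\\s+\\S", line)) {
      if (is.null(current)) next  # indented text outside a stanza: ignore
      tok <- strsplit(trimws(line), "\\s+")[[1L]]
      if (grepl('^"', tok[1L]) && length(current$members) == 0L) {
        current$description <- gsub('"', "", trimws(line))
        next
      }
      current$members[[length(current$members) + 1L]] <-
        list(raw = tok[1L], options = tok[-1L], line = ln)
      next
    }
    # Unindented directive we do not interpret (tablesIgnored, type, ...):
    # retained nowhere, no semantics.
  }
  flush()
  structure(list(variables = variables, stanzas = stanzas),
            class = "joiner_schema")
}

#' @export
print.joiner_schema <- function(x, ...) {
  cat(sprintf("<joiner schema: %d variable(s), %d identifier stanza(s)>\n",
              length(x$variables), length(x$stanzas)))
  invisible(x)
}

#' Overwrite a joiner variable
#'
#' Sets `$name` to `value` in the schema, returning the modified schema.
#' Because substitution happens at association-definition time, overwriting
#' a variable that holds a database list (conventionally `gbd`) re-scopes
#' which databases the link search considers.
#'
#' @param schema A [load_joiner()] schema.
#' @param name Variable name (without the `$`).
#' @param value Replacement text (may be a comma-separated database list).
#' @return The updated `joiner_schema`.
#' @export
joiner_set <- function(schema, name, value) {
  stopifnot(inherits(schema, "joiner_schema"))
  if (!is_scalar_string(name) || !is_scalar_string(value)) {
    stop_user("joiner variable name and value must be strings")
  }
  schema$variables[[name]] <- value
  schema
}

.joiner_substitute <- function(text, variables) {
  if (!length(variables)) return(text)
  for (nm in names(variables)[order(-nchar(names(variables)))]) {
    text <- gsub(paste0("$", nm), variables[[nm]], text, fixed = TRUE)
  }
  text
}

#' Expanded members of a stanza
#'
#' Applies the current variable values to a stanza's member references and
#' fans out comma-separated database lists. Used by [define_association()]
#' and handy for inspecting a schema.
#'
#' @param schema A [load_joiner()] schema.
#' @param stanza A stanza element of `schema$stanzas`, or its name.
#' @return A data.frame with columns `db`, `table`, `field`, `options`.
#' @export
joiner_members <- function(schema, stanza) {
  stopifnot(inherits(schema, "joiner_schema"))
  if (is.character(stanza)) {
    i <- match(stanza, vapply(schema$stanzas, `[[`, "", "name"))
    if (is.na(i)) stop_user("no identifier stanza named '%s'", stanza)
    stanza <- schema$stanzas[[i]]
  }
  out <- list()
  for (m in stanza$members) {
    ref <- .joiner_substitute(m$raw, schema$variables)
    parts <- strsplit(ref, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 3L || any(!nzchar(parts))) {
      stop_user("line %d: member '%s' is not of the form db.table.field",
                m$line, ref)
    }
    for (db in strsplit(parts[1L], ",", fixed = TRUE)[[1L]]) {
      out[[length(out) + 1L]] <- data.frame(db = db, table = parts[2L],
                                            field = parts[3L],
                                            options = paste(m$options, collapse = " "),
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(db = character(), table = character(),
                      field = character(), options = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

new_association <- function(table, local_field, target, remote_field,
                            cardinality, identifier = NA_character_) {
  structure(list(table = table, local_field = local_field,
                 target = target, remote_field = remote_field,
                 cardinality = cardinality, identifier = identifier),
            class = "ucsc_association")
}

#' @export
print.ucsc_association <- function(x, ...) {
  cat(sprintf("<association %s.%s -> %s.%s (%s)%s>\n",
              x$table$name, x$local_field, x$target$name, x$remote_field,
              x$cardinality,
              if (is.na(x$identifier)) "" else sprintf(" via '%s'", x$identifier)))
  invisible(x)
}

#' Define associations of a table from a joiner schema
#'
#' Scans every identifier stanza for members on table `t` (matching both
#' the table name and the label of the database `t` lives in). For each
#' such anchor, an association is created to every other member of the
#' stanza whose database is among the open handles and whose table exists
#' there; members on unconnected databases or undefined tables are silently
#' skipped, as are members whose field is missing from an existing table.
#' The operation is pure (idempotent) and restricting `open_dbs` can only
#' remove associations, never add them.
#'
#' @param schema A [load_joiner()] schema (variables as currently set).
#' @param t A [table_handle()].
#' @param open_dbs A list of [connect()] handles (or a single handle); each
#'   handle's `name` is matched against the schema's database components.
#' @return A list of `ucsc_association` objects (cardinality "many").
#' @export
define_association <- function(schema, t, open_dbs) {
  stopifnot(inherits(schema, "joiner_schema"), inherits(t, "ucsc_table"))
  if (inherits(open_dbs, "ucsc_db")) open_dbs <- list(open_dbs)
  db_names <- vapply(open_dbs, function(d) d$name, "")
  out <- list()
  seen <- character()
  for (stanza in schema$stanzas) {
    mem <- joiner_members(schema, stanza)
    anchors <- which(mem$table == t$name & mem$db == t$db$name)
    for (a in anchors) {
      if (!(mem$field[a] %in% t$columns$name)) next
      for (j in seq_len(nrow(mem))) {
        if (j == a) next
        k <- match(mem$db[j], db_names)
        if (is.na(k)) next  # unconnected database: skip
        db <- open_dbs[[k]]
        if (!DBI::dbExistsTable(db$con, mem$table[j])) next  # undefined table: skip
        target <- table_handle(db, mem$table[j])
        if (!(mem$field[j] %in% target$columns$name)) next
        key <- paste(mem$field[a], mem$db[j], mem$table[j], mem$field[j], sep = "\r")
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- new_association(t, mem$field[a], target,
                                                   mem$field[j], "many",
                                                   stanza$name)
      }
    }
  }
  out
}

#' Declare a table association manually
#'
#' Direct foreign-key association between two tables, independent of any
#' joiner schema: records of `t` link to records of `target` where
#' `remote_field` equals the record's `local_field` value. `kind = "one"`
#' navigates to at most one record (the first under the deterministic
#' ordering of [fetch_first()]); `kind = "many"` to all.
#'
#' @param t,target [table_handle()] objects.
#' @param kind `"one"` or `"many"`.
#' @param local_field,remote_field Reflected column names on `t` and
#'   `target` respectively.
#' @return A `ucsc_association`.
#' @export
declare_association <- function(t, kind = c("one", "many"), target,
                                local_field, remote_field) {
  kind <- match.arg(kind)
  stopifnot(inherits(t, "ucsc_table"), inherits(target, "ucsc_table"))
  check_field(t, local_field)
  check_field(target, remote_field)
  new_association(t, local_field, target, remote_field, kind)
}

#' Navigate an association from a record
#'
#' Returns the linked rows of the association's target table for one
#' record, always as a data.frame ("always an array"): zero rows when there
#' is no partner, one row for cardinality "one", all distinct matches for
#' "many".
#'
#' @param assoc A `ucsc_association` from [define_association()] or
#'   [declare_association()].
#' @param record A `ucsc_record`, named list, or one-row data.frame holding
#'   the association's local field.
#' @return A data.frame of target-table rows.
#' @export
linked_records <- function(assoc, record) {
  stopifnot(inherits(assoc, "ucsc_association"))
  if (inherits(record, "ucsc_record")) record <- unclass(record)
  if (is.data.frame(record)) {
    if (nrow(record) != 1L) stop_user("navigation expects exactly one record")
    record <- as.list(record)
  }
  if (!(assoc$local_field %in% names(record))) {
    stop_user("record has no field '%s'", assoc$local_field)
  }
  df <- find_all_by(assoc$target, assoc$remote_field, record[[assoc$local_field]])
  df <- unique(df)
  if (assoc$cardinality == "one" && nrow(df) > 1L) df <- df[1L, , drop = FALSE]
  df
}
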