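#' Construct a template instance
#'
#' An instance of a template fills some of its slots. Each slot holds an
#' ordered list of fillers: raw text strings for textual slots, nested
#' `template_instance`s for template-valued slots.
#'
#' @param template Template name.
#' @param fillers Named list mapping slot name to a list of fillers, each
#'   created with [text_filler()] or [instance_filler()]. Bare strings and bare
#'   `template_instance`s are promoted to fillers for convenience.
#' @return An object of class `template_instance`.
#' @export
#' @examples
#' template_instance("Medication", list(Drug = list("timolol")))
template_instance <- function(template, fillers = list()) {
  if (!is_string(template)) stopf("'template' must be a single name")
  if (length(fillers) && (is.null(names(fillers)) || any(names(fillers) == ""))) {
    stopf("'fillers' must be a named list keyed by slot name")
  }
  fillers <- lapply(fillers, function(fl) {
    if (!is.list(fl) || inherits(fl, "template_instance")) fl <- list(fl)
    lapply(fl, as_slot_filler)
  })
  if (length(fillers) == 0L) fillers <- list()   # drop stray names on empties
  structure(list(template = template, fillers = fillers), class = "template_instance")
}

#' Slot filler constructors
#'
#' A slot filler carries exactly one of a text string or a nested instance.
#'
#' @param text Non-empty character scalar.
#' @param instance A `template_instance`.
#' @return A `slot_filler`.
#' @export
text_filler <- function(text) {
  if (!is_string(text) || nchar(text) == 0L) stopf("textual fillers must be non-empty strings")
  structure(list(text = text), class = "slot_filler")
}

#' @rdname text_filler
#' @export
instance_filler <- function(instance) {
  if (!inherits(instance, "template_instance")) stopf("'instance' must be a template_instance")
  structure(list(instance = instance), class = "slot_filler")
}

as_slot_filler <- function(x) {
  if (inherits(x, "slot_filler")) return(x)
  if (inherits(x, "template_instance")) return(instance_filler(x))
  if (is_string(x)) return(text_filler(x))
  if (is.list(x) && !is.null(x$text)) return(text_filler(x$text))
  if (is.list(x) && !is.null(x$instance)) return(instance_filler(x$instance))
  stopf("cannot interpret object of class '%s' as a slot filler", class(x)[1])
}

#' Is a filler textual?
#' @param filler A `slot_filler`.
#' @return Logical scalar.
#' @export
is_text_filler <- function(filler) !is.null(filler$text)

#' @export
print.template_instance <- function(x, ...) {
  cat(sprintf("<template_instance> %s\n", x$template))
  cat(linearize_unchecked(canonicalize(x)), "\n")
  invisible(x)
}

#' Check that an instance conforms to a schema
#'
#' Recursively verifies that every filled slot exists in its template, that
#' filler kinds match the slot kind (and, for template-valued slots, that the
#' nested template is allowed), that filler counts lie within the slot's
#' `[min, max]` bounds, and that textual fillers are non-empty.
#'
#' @param inst A `template_instance`.
#' @param schema A `template_schema`.
#' @return `inst`, invisibly; errors with class `gcdecode_conform_error` otherwise.
#' @export
validate_instance <- function(inst, schema) {
  if (!inherits(inst, "template_instance")) stopf("not a template_instance")
  tn <- inst$template
  slots <- schema$templates[[tn]]
  if (is.null(slots)) {
    stopf("instance uses undefined template '%s'", tn, class = "gcdecode_conform_error")
  }
  for (sn in names(inst$fillers)) {
    sd <- find_slot(schema, tn, sn)
    if (is.null(sd)) {
      stopf("template '%s' has no slot '%s'", tn, sn, class = "gcdecode_conform_error")
    }
    fl <- inst$fillers[[sn]]
    if (length(fl) > sd$max) {
      stopf("slot '%s' of '%s': %d fillers exceed max_count %s", sn, tn, length(fl),
            format(sd$max), class = "gcdecode_conform_error")
    }
    for (f in fl) {
      if (is_text_filler(f)) {
        if (sd$kind != "textual") {
          stopf("slot '%s' of '%s': textual filler in template-valued slot", sn, tn,
                class = "gcdecode_conform_error")
        }
        if (nchar(f$text) == 0L) {
          stopf("slot '%s' of '%s': empty textual filler", sn, tn,
                class = "gcdecode_conform_error")
        }
      } else {
        if (sd$kind != "template") {
          stopf("slot '%s' of '%s': template filler in textual slot", sn, tn,
                class = "gcdecode_conform_error")
        }
        if (!f$instance$template %in% sd$templates) {
          stopf("slot '%s' of '%s': template '%s' not allowed here", sn, tn,
                f$instance$template, class = "gcdecode_conform_error")
        }
        validate_instance(f$instance, schema)
      }
    }
  }
  # min-count check covers unfilled slots too
  for (sd in slots) {
    n <- length(inst$fillers[[sd$name]])
    if (n < sd$min) {
      stopf("slot '%s' of '%s': %d fillers below min_count %d", sd$name, tn, n, sd$min,
            class = "gcdecode_conform_error")
    }
  }
  invisible(inst)
}

#' Canonicalize a template instance
#'
#' Sorts filled slots into canonical (byte lexicographic) order at every
#' nesting level and drops empty slot entries. Filler order within one slot is
#' preserved (it is part of the data). Idempotent; two instances that differ
#' only in slot insertion order become identical.
#'
#' @param inst A `template_instance`.
#' @return The canonical `template_instance`.
#' @export
canonicalize <- function(inst) {
  fl <- inst$fillers
  fl <- fl[lengths(fl) > 0L]
  if (length(fl) == 0L) fl <- list()             # normalize the empty map
  fl <- fl[sort_c(names(fl))]
  fl <- lapply(fl, function(slot_fillers) {
    lapply(slot_fillers, function(f) {
      if (is_text_filler(f)) f else instance_filler(canonicalize(f$instance))
    })
  })
  structure(list(template = inst$template, fillers = fl), class = "template_instance")
}

#' Test two instances for canonical equality
#'
#' @param a,b `template_instance`s.
#' @return TRUE iff the canonical forms are identical.
#' @export
instance_equal <- function(a, b) {
  identical(unclass_deep(canonicalize(a)), unclass_deep(canonicalize(b)))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Collect an instance together with all nested instances
#'
#' Flattens the nesting: returns the instance itself plus, recursively, every
#' instance filling one of its template-valued slots, in depth-first order.
#' This is the pooling used by corpus evaluation.
#'
#' @param inst A `template_instance`.
#' @return List of `template_instance`s.
#' @export
collect_instances <- function(inst) {
  out <- list(inst)
  for (fl in inst$fillers) {
    for (f in fl) {
      if (!is_text_filler(f)) out <- c(out, collect_instances(f$instance))
    }
  }
  out
}

# ---- JSON I/O ----

instance_to_list <- function(inst) {
  list(template = inst$template,
       fillers = lapply(inst$fillers, function(fl) {
         lapply(fl, function(f) {
           if (is_text_filler(f)) list(text = f$text)
           else list(instance = instance_to_list(f$instance))
         })
       }))
}

instance_from_list <- function(x) {
  fillers <- lapply(x$fillers, function(fl) {
    lapply(fl, function(f) {
      if (!is.null(f$text)) text_filler(f$text)
      else instance_filler(instance_from_list(f$instance))
    })
  })
  template_instance(x$template, fillers)
}

#' Read and write template instances as JSON
#'
#' The file holds either one instance object `{"template", "fillers"}` or an
#' array of them. `read_instances` always returns a list of instances.
#'
#' @param path File path.
#' @return `read_instances`: list of `template_instance`s.
#' @export
read_instances <- function(path) {
  if (!file.exists(path)) stopf("instance file not found: %s", path)
  doc <- jsonlite::read_json(path)
  if (!is.null(doc$template)) doc <- list(doc)
  lapply(doc, instance_from_list)
}

#' @rdname read_instances
#' @param instances A `template_instance` or list of them.
#' @export
write_instances <- function(instances, path) {
  if (inherits(instances, "template_instance")) instances <- list(instances)
  doc <- lapply(instances, instance_to_list)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
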