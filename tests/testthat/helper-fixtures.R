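# Small definition registries and handcrafted ODM strings used across the
# unit tests. Everything is built in code; no fixture files.

make_defs <- function(n_events = 2L, n_forms = 3L, n_groups = 4L,
                      n_items = 5L, mandatory = FALSE) {
  items <- lapply(seq_len(n_items), function(i)
    odm_item_def(sprintf("I%d", i), data_type = "integer"))
  groups <- lapply(seq_len(n_groups), function(g) list(
    oid = sprintf("IG%d", g), name = sprintf("IG%d", g),
    refs = lapply(sprintf("I%d", seq_len(n_items)),
                  odm_element_ref, mandatory = mandatory)))
  forms <- lapply(seq_len(n_forms), function(f) list(
    oid = sprintf("F%d", f), name = sprintf("F%d", f),
    refs = lapply(sprintf("IG%d", seq_len(n_groups)),
                  odm_element_ref, mandatory = mandatory)))
  events <- lapply(seq_len(n_events), function(e) list(
    oid = sprintf("SE%d", e), name = sprintf("SE%d", e),
    refs = lapply(sprintf("F%d", seq_len(n_forms)),
                  odm_element_ref, mandatory = mandatory)))
  odm_definitions(events, forms, groups, items)
}

# minimal well-formed ODM file with configurable oddities
mini_odm <- function(n_studies = 1L, n_mdv = 1L, value = "5",
                     odm_version = "1.3.2") {
  study <- paste0(
    ' <Study OID="ST1">\n',
    "  <GlobalVariables>\n",
    "   <StudyName>Mini</StudyName>\n",
    "   <StudyDescription>d</StudyDescription>\n",
    "   <ProtocolName>p</ProtocolName>\n",
    "  </GlobalVariables>\n",
    paste(replicate(n_mdv, paste0(
      '  <MetaDataVersion OID="MDV1" Name="v1">\n',
      "   <Protocol>\n",
      '    <StudyEventRef StudyEventOID="SE1" Mandatory="No"/>\n',
      "   </Protocol>\n",
      '   <StudyEventDef OID="SE1" Name="E" Repeating="No" Type="Scheduled">\n',
      '    <FormRef FormOID="F1" Mandatory="No"/>\n',
      "   </StudyEventDef>\n",
      '   <FormDef OID="F1" Name="F" Repeating="No">\n',
      '    <ItemGroupRef ItemGroupOID="IG1" Mandatory="No"/>\n',
      "   </FormDef>\n",
      '   <ItemGroupDef OID="IG1" Name="G" Repeating="No">\n',
      '    <ItemRef ItemOID="I1" Mandatory="No"/>\n',
      "   </ItemGroupDef>\n",
      '   <ItemDef OID="I1" Name="I" DataType="integer"/>\n',
      "  </MetaDataVersion>\n")), collapse = ""),
    " </Study>\n")
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<ODM xmlns="http://www.cdisc.org/ns/odm/v1.3" FileOID="FO"',
    ' FileType="Snapshot" CreationDateTime="2020-01-01T00:00:00"',
    ' ODMVersion="', odm_version, '">\n',
    paste(replicate(n_studies, study), collapse = ""),
    ' <ClinicalData StudyOID="ST1" MetaDataVersionOID="MDV1">\n',
    '  <SubjectData SubjectKey="S1">\n',
    '   <StudyEventData StudyEventOID="SE1">\n',
    '    <FormData FormOID="F1">\n',
    '     <ItemGroupData ItemGroupOID="IG1">\n',
    '      <ItemData ItemOID="I1" Value="', value, '"/>\n',
    "     </ItemGroupData>\n",
    "    </FormData>\n",
    "   </StudyEventData>\n",
    "  </SubjectData>\n",
    " </ClinicalData>\n",
    "</ODM>\n")
}

# one item per group, form shared across both events (positional reuse)
shared_form_odm <- function(values_se1, values_se2) {
  subj <- function(i, se, v) paste0(
    '  <SubjectData SubjectKey="P', se, ".", i, '">\n',
    '   <StudyEventData StudyEventOID="SE', se, '">\n',
    '    <FormData FormOID="F1">\n',
    '     <ItemGroupData ItemGroupOID="IG1">\n',
    '      <ItemData ItemOID="I1" Value="', v, '"/>\n',
    "     </ItemGroupData>\n    </FormData>\n   </StudyEventData>\n",
    "  </SubjectData>\n")
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<ODM xmlns="http://www.cdisc.org/ns/odm/v1.3" FileOID="FO"',
    ' FileType="Snapshot" CreationDateTime="2020-01-01T00:00:00"',
    ' ODMVersion="1.3.2">\n',
    ' <Study OID="ST1">\n',
    "  <GlobalVariables><StudyName>Shared</StudyName>",
    "<StudyDescription>d</StudyDescription>",
    "<ProtocolName>p</ProtocolName></GlobalVariables>\n",
    '  <MetaDataVersion OID="MDV1" Name="v1">\n',
    "   <Protocol>\n",
    '    <StudyEventRef StudyEventOID="SE1" Mandatory="No"/>\n',
    '    <StudyEventRef StudyEventOID="SE2" Mandatory="No"/>\n',
    "   </Protocol>\n",
    '   <StudyEventDef OID="SE1" Name="E1" Repeating="No" Type="Scheduled">\n',
    '    <FormRef FormOID="F1" Mandatory="No"/>\n',
    "   </StudyEventDef>\n",
    '   <StudyEventDef OID="SE2" Name="E2" Repeating="No" Type="Scheduled">\n',
    '    <FormRef FormOID="F1" Mandatory="No"/>\n',
    "   </StudyEventDef>\n",
    '   <FormDef OID="F1" Name="F" Repeating="No">\n',
    '    <ItemGroupRef ItemGroupOID="IG1" Mandatory="No"/>\n',
    "   </FormDef>\n",
    '   <ItemGroupDef OID="IG1" Name="G" Repeating="No">\n',
    '    <ItemRef ItemOID="I1" Mandatory="No"/>\n',
    "   </ItemGroupDef>\n",
    '   <ItemDef OID="I1" Name="I" DataType="integer"/>\n',
    "  </MetaDataVersion>\n </Study>\n",
    ' <ClinicalData StudyOID="ST1" MetaDataVersionOID="MDV1">\n',
    paste(mapply(subj, seq_along(values_se1), 1L, values_se1),
          collapse = ""),
    paste(mapply(subj, seq_along(values_se2), 2L, values_se2),
          collapse = ""),
    " </ClinicalData>\n</ODM>\n")
}

item_stats_by_path <- function(report_or_stats) {
  st <- if (inherits(report_or_stats, "odm_analysis_report"))
    report_or_stats$statistics else report_or_stats
  items <- Filter(function(e) e$level == "item", st$elements)
  names(items) <- vapply(items, function(e) paste(e$path, collapse = "/"),
                         "")
  items
}

nodes_by_path <- function(cp) {
  stats::setNames(cp$nodes, vapply(cp$nodes, function(n)
    paste(n$path, collapse = "/"), ""))
}
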