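# Packaged fixtures

## table1_orf1_domains.tsv

A cell-for-cell transcription of the published per-subgroup summary table of
ORF1 domains in Jockey-superfamily LINEs: 20 subgroups (10 L2, 2 Jockey,
8 CR1), one row per (subgroup, domain) pair. Columns:

- `subgroup_id`, `lineage` — subgroup name (e.g. `L2_3`) and its lineage.
- `n_seqs` — number of full-length elements in the subgroup.
- `rt_identity_pct` — mean pairwise amino-acid identity of the reverse
  transcriptase within the subgroup.
- `type_subtype` — the ORF1 type/subtype assigned in the source study
  (blank for CR1_8, which was left unassigned there).
- `domain_label` — `PHD`, `RRM`, `CCHC`, `Tnp22`, `Esterase`, `CC`, `lz`,
  `zf`, or `none` for a subgroup with no identified domains.
- `length_aa` — minimum identified domain length (aa).
- `aa_identity_pct` — mean pairwise amino-acid identity of the domain
  alignment.
- `top_hit`, `probability_pct` — best profile-database hit and its
  reported probability.
- `n_copies` — domain copy number per element, where reported.

Blank cells in the source are encoded as `NA`, never as 0.

### Element-count reconciliation

The source text reports 451 complete elements (235 CR1, 87 Jockey, 129 L2),
of which 3 that fell into no subgroup (1 CR1, 2 L2) were set aside, leaving
448 analysed. Summing `n_seqs` over the 20 subgroups gives exactly
448 = 234 CR1 + 87 Jockey + 127 L2, consistent with that arithmetic. Note
that two of the four L2_8 elements lack an identifiable ORF1 start but are
still counted in `n_seqs`; the table's own total is therefore 448, and that
is the figure the package asserts.

Rows within a subgroup are listed in N-to-C (5' to 3') domain order, so the
ordered `domain_label` sequence of a subgroup is its ORF1 architecture.
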