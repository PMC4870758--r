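# opsinsites

Candidate spectral-tuning-site analysis for duplicated insect opsins.

Many insects tune the peak spectral sensitivity (λmax) of their visual
pigments not by carrying extra opsin classes but by duplicating an existing
class (ultraviolet-sensitive, UVS, or long-wavelength-sensitive, LWS) and
accumulating amino-acid substitutions between the copies — especially in the
chromophore binding pocket (CBP), the shell of residues within 4 Å of the
retinal chromophore. `opsinsites` is for molecular evolutionists who have a
set of opsin paralogs (plus, optionally, branch-site positive-selection
results and a homology model) and want a reproducible screen for the sites
most likely to shift λmax.

## What it computes

A site is a **candidate spectral-tuning site** when, on reference
(bovine-rhodopsin-style) numbering, any of three clauses fires:

1. the site is under branch-site positive selection (ω = dN/dS > 1 on a
   foreground branch, evaluated by an LRT against the ω = 1 null) in an
   opsin paralog;
2. a homologous site in another organism is under positive selection or
   carries a documented λmax shift;
3. the site lies in the CBP and the paralog substitution is *structurally
   significant*.

Structural significance is categorical: a substitution gains/loses
side-chain **size** when the non-hydrogen side-chain atom counts differ by
≥ 2 (G0 A1 S2 C2 T3 V3 P3 L4 I4 M4 N4 D4 Q5 E5 K5 H6 R7 F7 Y8 W10);
**charge** labels fire on transitions into/out of the positive {K,R,H} or
negative {D,E} classes (and suppress plain polarity labels); **polarity**
labels on polar {S,T,C,Y,N,Q} ↔ nonpolar transitions; plus **disulfide
potential** (cysteine) and **backbone rigidity/flexibility** (proline)
labels. Anything else is "most likely insignificant".

Supporting statistics: paralog percent similarity — columns identical or
scoring ≥ 1 under BLOSUM62, divided by the number of residue-bearing
columns — and CBP membership from atomic coordinates by the minimum
residue–retinal distance rule (≤ 4 Å, boundary included).

## Worked example

```r
library(opsinsites)

# substitution significance, e.g. alanine -> glutamine
classify_substitution("A", "Q")$kind
#> [1] "increase_in_size" "gain_of_polarity"

# the packaged combined-evidence screen (UVS + LWS paralog tables)
sc <- screen_candidates(load_evidence_table())
sc
#> Candidate spectral-tuning sites: 30
#>   UVS (15): 12, 105, 107, 118, 125, 137, 172, 186, 188, 207, 242^a, 261, 272, 293, 294
#>   LWS (15): 44, 46, 91, 93, 122, 123, 156, 164, 170, 197, 211, 242^a, 269, 274, 281
summary(sc)
#> UVS: 15 candidates; 5 in binding pocket {118,186,188,207,261}; 5 non-pocket paralog-wide {105,107,137,242^a,294}
#> LWS: 15 candidates; 3 in binding pocket {122,211,269}; 3 non-pocket paralog-wide {46,123,274}
```

The screen finds 15 UVS and 15 LWS candidate sites. Within each class the
summary partitions candidates into binding-pocket sites (where substitutions
can act directly on retinal) and non-pocket sites whose positive selection
spans a whole paralog clade ("paralog-wide" branches; site `242^a` is an
insertion between reference positions 242 and 243). Together these point to
how buprestid beetles may have regained short-wavelength sensitivity from
UVS/LWS duplicates despite lacking a blue opsin class.

Percent similarity and pocket detection:

```r
gen <- generate_paralog_pair(300, conserved_fraction = 0.8, seed = 1)
percent_similarity(gen$alignment)
#> [1] 80

toy <- generate_toy_structure(10, planted_pocket = c(2, 5, 8), seed = 3)
pocket <- binding_pocket(read_structure(text = toy$pdb))
pocket$residue_seq[pocket$in_pocket]
#> [1] 2 5 8
```

`run_pipeline(out_dir = "...")` composes the stages end to end and writes
`candidates.tsv`, `counts.json` and a run manifest;
`inst/scripts/opsin_screen.R` wraps it for shell use.

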