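# junctionscape

Splice junctions sit inside protein-coding sequence, so the nucleotide
signals that make splicing efficient are also protein-coding constraints.
`junctionscape` is an R package for analysing that interplay across three
connected questions:

1. **What amino acids does the splice-site consensus encode?** The
   canonical exonic signal — `AG` immediately before the 5′ splice site
   and `G` immediately after the 3′ splice site — fixes nucleotides of the
   last codon of each exon (or of the codon split across the junction by a
   phase 1/2 intron). The package maps every exon to its encoded residues,
   annotates start/end phases (cumulative coding nucleotides mod 3),
   extracts each junction's last-codon amino acid, and compares the
   resulting composition with the proteome background as fold changes and
   as a 2×2 chi-square on the ten most vs least disorder-promoting amino
   acids of the TOP-IDP scale.
2. **How does amino-acid usage vary with distance from the junction?**
   After the classic filtering rules (start codon, stop codon, no premature
   stop, no uncertain base, length divisible by three; first/last exons
   dropped; incomplete edge codons trimmed), usage of each amino acid is
   tabulated at codon distances 2–34 from each exon edge and correlated
   with distance by Spearman's rank correlation (significance at
   p ≤ 0.001), separately for structure- and disorder-encoding exons and
   per phase, with per-genome profiles poolable by taxonomic group.
3. **Where do exonic splicing enhancers (ESEs) sit?** Hexamer motif sets
   (RESCUE-ESE–style, 238 motifs; INT3-style consensus, 84) are scanned
   over the same codon 2–34 windows with a stride-1 sliding window, and
   match densities are compared between exon classes and between
   constituent and alternative exons, alongside a Welch t comparison of
   flanking intron lengths.

Exons are classified from per-residue annotation tracks (disorder
consensus and predicted domain membership, in the style of D²P² and
SUPERFAMILY assignments): *disorder-encoding* if ≥ 75% of encoded residues
are consensus-disordered and none is in a domain, *structure-encoding* if
≥ 75% are in a domain and none is disordered, otherwise *other*.

Because the real inputs are genome-scale downloads, the package ships a
first-class **synthetic genome generator** (`gen_config()`,
`generate_genome()`): seeded, deterministic gene models with configurable
splice-site bias β, planted per-class ESE rates, exon-aligned
disorder/domain tracks, composition gradients near junctions, alternative
transcripts by exon skipping, and injectable filter defects — every
planted signal recorded in a ground-truth table so each analysis stage has
a recoverable target.

## Worked example

```r
library(junctionscape)

cfg    <- gen_config(n_genes = 120, seed = 42)   # default study conditions
bundle <- generate_genome(cfg)

cls <- classify_exons(bundle$transcripts, bundle$tracks)
jr  <- junction_residues(bundle$transcripts)
bg  <- background_composition(bundle$transcripts)
jt  <- junction_composition(jr, by = "all")$all

disorder_set_enrichment(jt, bg)
#> <jx_enrichment> set of 10 amino acids {PEKSQHDRGA}
#>   junction: 82.6%  vs  background: 56.0%
#>   chi-square = 286.9, df = 1, p = 2.4e-64

fc <- fold_change(jt, bg)
head(fc[order(-fc$fold), ], 5)
#>   amino_acid junction_freq background_freq     fold
#> 5          Q     0.1574803      0.02791073 5.642286
#> 3          K     0.1259843      0.03139957 4.012292
#> 2          E     0.1328740      0.03359105 3.955637
#> 9          G     0.1486220      0.06891776 2.156513
#> 8          R     0.1387795      0.10301723 1.347149

fl <- filter_for_correlation(bundle$transcripts)
fl
#> <jx_filter> 143/143 transcripts pass; 873 internal exons retained
win <- junction_windows(fl$exons)
ese_density(win, cls, bundle$motifs$rescue)
#>              motif_set status   category n_windows n_matches density_pct
#>  rescue-like-synthetic    all        all    111322     12522    11.24845
#>  rescue-like-synthetic    all structured     54532      5471    10.03264
#>  rescue-like-synthetic    all disordered     31682      4294    13.55344
#>  rescue-like-synthetic    all      other     25108      2757    10.98056
#> structured vs disordered:  chi-square 247.3, df 1, p = 9.9e-56

flanking_intron_comparison(bundle$transcripts, cls)
#> <jx_intron_test> structured 992.7 nt (n=423) vs disordered 673.2 nt (n=247)
#>   Welch t = 23.99, df = 540.8, p = 3.54e-87
```

Reading the output: with the default splice-site bias (β = 0.6) the
junction's last codons land overwhelmingly on Glutamine, Lysine, Glutamic
acid (phase 0: `NAG` codons), Glycine (phase 1) and Arginine (phase 2:
`AGG`), all but Arginine strongly disorder-promoting — so 82.6% of
junction residues fall in the disorder-promoting half of the alphabet
against 56.0% in the background. The ESE scan recovers the planted 10% vs
13.5% window match rates in structure- vs disorder-encoding exons, and
disorder-encoding exons sit between significantly shorter introns, exactly
as planted.

The same stages are scriptable end to end:

```r
run_pipeline("all", config = run_config(gen_config(n_genes = 120, seed = 42)),
             out_dir = "out")   # TSV reports + manifest.json under out/
```

or from a shell via `Rscript inst/cli/junctionscape.R all --out out --seed 42`.

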