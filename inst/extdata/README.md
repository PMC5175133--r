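# Bundled data files

`depdc_primer_panel.fasta` — the published human DEPDC qPCR primer panel
(forward/reverse primers for DEPDC1–DEPDC7 plus beta-actin), used by the
primer %GC worked examples and the acceptance script.

All `synthetic_*` files are generated by the package's own simulators and
stand in for database downloads in examples. Regenerate with:

```sh
profam simulate family --n 12 --min-len 60 --max-len 120 \
  --bias-residues KRDE --bias-strength 0.18 --prefix fam --seed 11 synthetic_family_pos.fasta
profam simulate family --n 12 --min-len 60 --max-len 120 \
  --prefix bg --seed 12 synthetic_family_neg.fasta
profam simulate alignment --clades 3 --leaves 2 --length 120 \
  --within 0.03 --between 0.4 --seed 6 synthetic_alignment.fasta
profam simulate ct --n 8 --genes DEPDC1B,DEPDC7 --effect -2.5 \
  --noise 0.8 --seed 5 synthetic_ct.csv
```
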