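# GenBank cache

The real-data acceptance tests read GenBank flat files from this
directory. This sandbox has no network access, so the records must be
downloaded beforehand, e.g.:

    for acc in MW929088 MW929089 MW929090 MW929091 \
               MN356232 NC_027933; do
      curl -o "$acc.gb" \
        "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=nuccore&id=$acc&rettype=gb&retmode=text"
    done

Optionally also add the *Motacilla tschutschensis* mitogenome record —
any additional `.gb` file placed here joins the comparative set
automatically.

Place the files here as `<accession>.gb` **before** installing the
package; the tests locate them with `system.file()`. When absent, the
corresponding tests fail with the same instructions.
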