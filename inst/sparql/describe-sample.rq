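PREFIX obo: <http://purl.obolibrary.org/obo/>
PREFIX dc: <http://purl.org/dc/elements/1.1/>
PREFIX ro: <http://www.obofoundry.org/ro/ro.owl#>
DESCRIBE ?rep ?obs ?data ?samp
WHERE {
   ?samp dc:title "{{SAMPLE}}" .
   # IAO_0000136 = 'is_about'
   ?obs obo:IAO_0000136 ?samp .
   ?obs ro:part_of ?data .
   ?obs obo:IAO_0000136 ?rep .
}
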