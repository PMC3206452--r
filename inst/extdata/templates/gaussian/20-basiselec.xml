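<?xml version="1.0" encoding="UTF-8"?>
<!-- Basis-set size and electron counts (link 301 style summary). -->
<template id="basiselec" pattern="\s*[0-9]+ basis functions,.*" section="initialization">
  <record id="basis">\s*{1I, g:basiscount} basis functions,\s+{1I, g:primbasis} primitive gaussians.*</record>
  <record id="electrons">\s*{1I, g:alphae} alpha electrons\s+{1I, g:betae} beta electrons.*</record>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:basiscount']" value="cc:basiscount"/>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:alphae']" value="cc:alphae"/>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:betae']" value="cc:betae"/>
</template>
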