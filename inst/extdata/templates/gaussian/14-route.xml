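<?xml version="1.0" encoding="UTF-8"?>
<!-- Route line: model chemistry (method/basis) and job keywords. -->
<template id="route" pattern="\s*#N .*" section="initialization">
  <record id="route">\s*#N {X, g:method}/{X, g:basis}\s{A, g:keywords}</record>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:method']" value="cc:method"/>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:basis']" value="cc:basis"/>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:keywords']" value="g:keyword"/>
</template>
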