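<?xml version="1.0" encoding="UTF-8"?>
<!-- Program banner: opens a new job (program restart marker). -->
<template id="jobhead" pattern="\s*Entering Gaussian System.*"
          section="environment" jobstart="true">
  <record id="entering">\s*Entering Gaussian System, Link 0=.*</record>
  <record id="progver">\s*{X, g:program}:\s+{X, g:version}\s+{A, g:progdate}</record>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:program']" value="cc:program"/>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:version']" value="cc:version"/>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:progdate']" value="cc:program.date"/>
</template>
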