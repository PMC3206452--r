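<?xml version="1.0" encoding="UTF-8"?>
<template id="termination" pattern="\s*Normal termination of .*" section="finalization">
  <record id="term">\s*Normal termination of {X, g:prog} at {A, g:endtime}</record>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:endtime']" value="g:jobdatetime.end"/>
  <transform process="delete" xpath=".//cml:scalar[@cmlx:temp='g:prog']"/>
</template>
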